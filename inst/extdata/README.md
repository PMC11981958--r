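# External data

This package ships no data files; every test fixture is generated in
code and the synthetic generator (`simulate_study()`) produces complete
input bundles on demand.

To run the survey-reproduction checks in the test suite against the
published tables, place the journal article's Supporting Information,
converted to plain text, under `supplement/` here as:

* `incidence.tsv` — site x ASV 0/1 table (first column `site`)
* `traits.tsv`    — `asv_id` plus the nine morphological ratio columns
* `lineage.tsv`   — `asv_id`, `order` (and further ranks if available)
* `sequences.fasta` — per-ASV amplicon sequences, aligned within order
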