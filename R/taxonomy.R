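#' Build a taxonomic reference database
#'
#' @param records Data frame from [read_fasta()] (columns `id`, `seq`).
#' @param lineage Data frame with columns `id`, `species`, `genus`,
#'   `family`, `order` and logical `native`; every record id must have a
#'   complete four-rank lineage.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(records, lineage) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  need <- c("id", "species", "genus", "family", "order", "native")
  if (!all(need %in% names(lineage))) {
    stop("lineage needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(records$id, lineage$id)
  if (length(miss)) {
    stop("lineage missing for reference record(s): ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  lineage <- lineage[match(records$id, lineage$id), ]
  if (any(!complete.cases(lineage[, c("species", "genus", "family", "order")]))) {
    stop("every reference record needs a complete 4-rank lineage", call. = FALSE)
  }
  structure(list(records = records, lineage = lineage), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference DB:", nrow(x$records), "records,",
      length(unique(x$lineage$species)), "species (",
      sum(x$lineage$native), "native records )\n")
  invisible(x)
}

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment scored to maximise the match count
#' (match 1, mismatch 0, near-zero gap cost); identity is the number of
#' matched columns divided by the total alignment columns.
#'
#' @param a,b Nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  alignment_identity_many(a, b)
}

#' Vectorised identity of one query against many subjects
#' @noRd
alignment_identity_many <- function(a, subjects) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(subjects), Biostrings::DNAString(a),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 1e-3)
  Biostrings::nmatch(aln) /
    Biostrings::width(Biostrings::alignedPattern(aln))
}

#' In-silico PCR against reference sequences
#'
#' Locates a forward-primer site and a downstream reverse-primer site
#' (reverse primer given 5'->3', matched as its reverse complement) on
#' either strand of each reference, allowing up to `max_mismatch`
#' IUPAC-aware mismatches per primer, and extracts the inter-primer
#' amplicon when its length falls in `[min_len, max_len]`. When several
#' primer-site combinations qualify, the one with the fewest total
#' mismatches (then the longest amplicon) is kept; at most one amplicon is
#' emitted per reference.
#'
#' @param refs Data frame of sequences (columns `id`, `seq`).
#' @param fwd,rev Primer strings (IUPAC codes allowed), both 5'->3'.
#' @param min_len,max_len Amplicon length window in bp.
#' @param max_mismatch Per-primer mismatch budget.
#' @return Data frame `id`, `seq`, `length` of extracted amplicons;
#'   references without a qualifying amplicon are dropped. References
#'   shorter than a primer are skipped silently.
#' @export
insilico_pcr <- function(refs, fwd, rev, min_len = 150L, max_len = 220L,
                         max_mismatch = 3L) {
  fwd_p <- Biostrings::DNAString(toupper(fwd))
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev)))
  hit_sites <- function(p, s) {
    h <- Biostrings::matchPattern(p, s, max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = FALSE)
    if (length(h) == 0) return(NULL)
    mm <- Biostrings::neditStartingAt(p, s, starting.at = Biostrings::start(h),
                                      with.indels = FALSE, fixed = FALSE)
    data.frame(start = Biostrings::start(h), end = Biostrings::end(h), mm = mm)
  }
  out <- lapply(seq_len(nrow(refs)), function(i) {
    subject <- Biostrings::DNAString(refs$seq[i])
    if (length(subject) < max(length(fwd_p), length(rev_rc))) return(NULL)
    best <- NULL
    for (s in list(subject, Biostrings::reverseComplement(subject))) {
      fh <- hit_sites(fwd_p, s)
      rh <- hit_sites(rev_rc, s)
      if (is.null(fh) || is.null(rh)) next
      for (fi in seq_len(nrow(fh))) {
        for (ri in seq_len(nrow(rh))) {
          if (rh$start[ri] <= fh$end[fi]) next
          amp_len <- rh$start[ri] - fh$end[fi] - 1L
          if (amp_len < min_len || amp_len > max_len) next
          tot_mm <- fh$mm[fi] + rh$mm[ri]
          if (is.null(best) || tot_mm < best$mm ||
              (tot_mm == best$mm && amp_len > best$len)) {
            best <- list(mm = tot_mm, len = amp_len,
                         seq = as.character(Biostrings::subseq(
                           s, fh$end[fi] + 1L, rh$start[ri] - 1L)))
          }
        }
      }
    }
    if (is.null(best)) return(NULL)
    data.frame(id = refs$id[i], seq = best$seq, length = best$len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(), seq = character(), length = integer())
  }
  out
}

#' Best reference hit for an ASV
#'
#' @param asv_seq Query nucleotide string.
#' @param refs A [reference_db()] (or any data frame with `id`, `seq`).
#' @return List with `id` (best record, ties broken lexicographically) and
#'   `identity`.
#' @export
best_identity <- function(asv_seq, refs) {
  records <- if (inherits(refs, "reference_db")) refs$records else refs
  if (nrow(records) == 0) stop("empty reference set", call. = FALSE)
  idents <- alignment_identity_many(asv_seq, records$seq)
  best <- max(idents)
  hits <- records$id[idents >= best - 1e-12]
  list(id = sort(hits)[1], identity = best)
}

#' Hierarchical identity-banded taxonomic assignment
#'
#' Two passes. First, an ASV identical (identity 1.0) to any native-species
#' reference is assigned that species directly (`source = "native"`).
#' Otherwise the best global hit is banded by identity: >= 0.98 species,
#' 0.96--0.98 genus, 0.90--0.96 family, < 0.90 order (lower bounds closed).
#' When several hits tie at the best identity, the assignment is their
#' lowest common ancestor at or above the band's rank; if they disagree
#' even at order, the ASV is `unassigned`.
#'
#' @param asv_seq Query sequence string.
#' @param refs A [reference_db()].
#' @param cfg A [run_config()] carrying the band cutoffs.
#' @return One-row data frame: `rank`, `name`, `identity`, `source`, and
#'   `order` (the order-level ancestor of the assignment, `NA` if
#'   unassigned).
#' @export
assign_taxonomy <- function(asv_seq, refs, cfg = run_config()) {
  stopifnot(inherits(refs, "reference_db"))
  lin <- refs$lineage
  # pass 1: exact native match, species level only
  nat <- which(lin$native)
  if (length(nat)) {
    nat_id <- alignment_identity_many(asv_seq, refs$records$seq[nat])
    if (max(nat_id) >= 1 - 1e-12) {
      hit <- nat[nat_id >= 1 - 1e-12]
      hit <- hit[order(lin$id[hit])][1]
      return(data.frame(rank = "species", name = lin$species[hit],
                        identity = 1, source = "native",
                        order = lin$order[hit], stringsAsFactors = FALSE))
    }
  }
  # pass 2: banded best global hit
  idents <- alignment_identity_many(asv_seq, refs$records$seq)
  v <- max(idents)
  tied <- which(idents >= v - 1e-9)
  band <- if (v >= cfg$id_species) "species" else if (v >= cfg$id_genus) {
    "genus"
  } else if (v >= cfg$id_family) "family" else "order"
  ranks <- c("species", "genus", "family", "order")
  for (r in ranks[seq(match(band, ranks), 4)]) {
    names_r <- unique(lin[[r]][tied])
    if (length(names_r) == 1) {
      return(data.frame(rank = r, name = names_r, identity = v,
                        source = "global", order = unique(lin$order[tied])[1],
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(rank = "unassigned", name = NA_character_, identity = v,
             source = "global", order = NA_character_,
             stringsAsFactors = FALSE)
}

#' Assign every ASV of a table
#'
#' @param table An [asv_table()] with sequences.
#' @param refs A [reference_db()].
#' @param cfg A [run_config()].
#' @return Data frame with one row per ASV: `asv_id`, `rank`, `name`,
#'   `identity`, `source`, `order`.
#' @export
assign_taxonomy_table <- function(table, refs, cfg = run_config()) {
  ids <- rownames(table$counts)
  res <- do.call(rbind, lapply(ids, function(a) {
    assign_taxonomy(table$sequences[[a]], refs, cfg)
  }))
  cbind(data.frame(asv_id = ids, stringsAsFactors = FALSE), res)
}

#' Fish gate from an order list
#'
#' An ASV counts as fish when the order-level lineage of its assignment is
#' in the supplied list of fish orders.
#'
#' @param assignments Output of [assign_taxonomy_table()].
#' @param fish_orders Character vector of order names regarded as fish.
#' @return Named logical vector by ASV id, suitable for [filter_asvs()].
#' @export
is_fish_by_order <- function(assignments, fish_orders) {
  setNames(!is.na(assignments$order) & assignments$order %in% fish_orders,
           assignments$asv_id)
}
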