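#' Nucleotide diversity of aligned sequences
#'
#' Mean proportion of differing positions over all unordered sequence
#' pairs. Sequences must be equal length (aligned). For each pair,
#' positions where both sequences carry a gap (`-`) are dropped from the
#' pair's denominator; a gap opposite a base counts as a difference.
#'
#' @param seqs Character vector of >= 2 equal-length sequences.
#' @return Nucleotide diversity (substitutions per site), or `NA` when
#'   fewer than two sequences are given.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2) return(NA_real_)
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("nucleotide_diversity() needs equal-length (aligned) sequences",
         call. = FALSE)
  }
  gap <- utf8ToInt("-")
  chars <- lapply(toupper(seqs), utf8ToInt)
  n <- length(seqs)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both_gap <- chars[[i]] == gap & chars[[j]] == gap
      len <- L - sum(both_gap)
      if (len == 0) next
      acc <- acc + sum(chars[[i]] != chars[[j]] & !both_gap) / len
    }
  }
  acc / (n * (n - 1) / 2)
}

#' Per-site genetic diversity as mean per-order nucleotide diversity
#'
#' For each site, nucleotide diversity is computed within every taxonomic
#' order represented there by at least two ASVs, and the site's genetic
#' diversity is the unweighted mean of those per-order values. Orders with
#' fewer than two present ASVs are ignored; a site with no eligible order
#' is `NA`.
#'
#' @param incidence Site x ASV 0/1 matrix.
#' @param sequences Named character vector of (aligned, equal-length within
#'   order) ASV sequences.
#' @param assignments Data frame with `asv_id` and `order` columns, e.g.
#'   from [assign_taxonomy_table()].
#' @return Named numeric vector of GD per site.
#' @export
site_genetic_diversity <- function(incidence, sequences, assignments) {
  order_of <- setNames(assignments$order, assignments$asv_id)
  gd <- setNames(rep(NA_real_, nrow(incidence)), rownames(incidence))
  for (s in rownames(incidence)) {
    present <- colnames(incidence)[incidence[s, ] > 0]
    present <- present[!is.na(order_of[present])]
    if (!length(present)) next
    pis <- tapply(present, order_of[present], function(asvs) {
      if (length(asvs) < 2) return(NA_real_)
      nucleotide_diversity(unname(sequences[asvs]))
    })
    pis <- pis[!is.na(pis)]
    if (length(pis)) gd[s] <- mean(pis)
  }
  gd
}
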