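#' Hamming distance between two equal-length sequences
#' @noRd
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Are two sequences within a single edit (substitution or indel)?
#'
#' Equal lengths are compared by Hamming distance; lengths differing by one
#' are compared by a single-deletion scan. Larger length differences are
#' never within distance 1.
#' @noRd
within_d1 <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (a == b) return(TRUE)
  if (la == lb) return(hamming(a, b) <= 1L)
  if (abs(la - lb) != 1L) return(FALSE)
  long <- if (la > lb) a else b
  short <- if (la > lb) b else a
  x <- utf8ToInt(long); y <- utf8ToInt(short)
  # first position where they disagree; deleting it from the long sequence
  # must make them identical
  n <- length(y)
  i <- 1L
  while (i <= n && x[i] == y[i]) i <- i + 1L
  identical(x[-i], y)
}

#' Dereplicate reads into an ASV table
#'
#' Collapses identical sequences, summing their multiplicities per
#' site-replicate sample. ASV ids are assigned `asv_00001`, ... in order of
#' decreasing total reads (ties by sequence, lexicographically).
#'
#' @param records Data frame with columns `seq` (nucleotide string),
#'   `sample` (a `<site>_r<k>` sample name) and `count` (positive integer
#'   multiplicity; defaults to 1 when absent).
#' @return An [asv_table()] with one row per unique sequence.
#' @export
dereplicate <- function(records) {
  stopifnot(is.data.frame(records), all(c("seq", "sample") %in% names(records)))
  if (is.null(records$count)) records$count <- 1L
  records$seq <- toupper(records$seq)
  ag <- aggregate(count ~ seq + sample, data = records, FUN = sum)
  samples <- sort(unique(ag$sample))
  seqs <- unique(ag$seq)
  m <- matrix(0L, nrow = length(seqs), ncol = length(samples),
              dimnames = list(seqs, samples))
  m[cbind(match(ag$seq, seqs), match(ag$sample, samples))] <- as.integer(ag$count)
  ord <- order(-rowSums(m), rownames(m))
  m <- m[ord, , drop = FALSE]
  ids <- sprintf("asv_%05d", seq_len(nrow(m)))
  sequences <- setNames(rownames(m), ids)
  rownames(m) <- ids
  asv_table(m, sequences = sequences)
}

#' Single-linkage clustering of ASVs at edit distance 1
#'
#' Agglomerates sequences that are connected by chains of single-nucleotide
#' differences (one substitution, or one insertion/deletion for lengths
#' differing by one), in the manner of single-linkage swarming with d = 1.
#' Clusters are seeded from the most abundant unassigned sequence; the
#' representative of each cluster is its most abundant member (ties broken
#' by ASV id) and member counts are summed onto it.
#'
#' @param table An [asv_table()] with sequences.
#' @return An [asv_table()] of cluster representatives; the grand total
#'   read count is preserved.
#' @export
cluster_d1 <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$sequences)) stop("cluster_d1() needs sequences", call. = FALSE)
  n <- nrow(table$counts)
  if (n <= 1) return(table)
  tot <- total_reads(table)
  ids <- rownames(table$counts)
  ord <- order(-tot, ids)          # most-abundant-first, deterministic
  assigned <- rep(NA_integer_, n)
  n_clust <- 0L
  seqs <- unname(table$sequences[ids])
  lens <- nchar(seqs)
  for (s in ord) {
    if (!is.na(assigned[s])) next
    n_clust <- n_clust + 1L
    queue <- s
    assigned[s] <- n_clust
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cand <- which(is.na(assigned) & abs(lens - lens[cur]) <= 1L)
      for (j in cand) {
        if (within_d1(seqs[cur], seqs[j])) {
          assigned[j] <- n_clust
          queue <- c(queue, j)
        }
      }
    }
  }
  rep_of <- vapply(seq_len(n_clust), function(k) {
    members <- which(assigned == k)
    members[order(-tot[members], ids[members])][1]
  }, integer(1))
  m <- rowsum(table$counts, group = assigned, reorder = TRUE)
  rownames(m) <- ids[rep_of]
  m <- m[order(rownames(m)), , drop = FALSE]
  asv_table(m, sequences = table$sequences[rownames(m)])
}

#' Filter ASVs on reads, length, fish status and relative abundance
#'
#' A single deletion pass retaining exactly the ASVs with total reads
#' >= `min_reads`, length within `[min_len, max_len]`, a fish assignment,
#' and relative abundance >= `min_freq`. Relative abundance uses the
#' pre-filter grand total as denominator; the filter is not iterated.
#'
#' @param table An [asv_table()] with sequences.
#' @param is_fish Named logical vector (by ASV id); ASVs absent from it are
#'   treated as non-fish.
#' @param cfg A [run_config()].
#' @return The filtered [asv_table()]; warns if nothing survives.
#' @export
filter_asvs <- function(table, is_fish, cfg = run_config()) {
  stopifnot(inherits(table, "asv_table"))
  ids <- rownames(table$counts)
  tot <- total_reads(table)
  freq <- tot / sum(tot)
  len <- nchar(table$sequences[ids])
  fish <- ids %in% names(is_fish)[is_fish]
  keep <- tot >= cfg$min_reads & len >= cfg$min_len & len <= cfg$max_len &
    fish & freq >= cfg$min_freq
  if (!any(keep)) {
    warning("filter_asvs(): no ASV passed the filter cascade", call. = FALSE)
  }
  asv_table(table$counts[keep, , drop = FALSE],
            sequences = table$sequences[ids[keep]])
}

#' Pairwise sequence identities of an ASV table
#'
#' Identity for every ASV pair, as used by [lulu_curate()]. Equal-length
#' pairs (the normal case for a fixed amplicon) are compared without gaps,
#' identity `(L - Hamming) / L`; pairs of differing length fall back to
#' global-alignment identity ([alignment_identity()]).
#'
#' @param table An [asv_table()] with sequences.
#' @return A symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
pairwise_identity <- function(table) {
  ids <- rownames(table$counts)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2) return(m)
  seqs <- unname(table$sequences[ids])
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    grp <- which(lens == L)
    if (length(grp) < 2) next
    b <- vapply(seqs[grp], utf8ToInt, integer(L))  # L x k byte matrix
    for (j in seq(2, length(grp))) {
      prev <- seq_len(j - 1)
      h <- colSums(b[, prev, drop = FALSE] != b[, j])
      m[grp[prev], grp[j]] <- m[grp[j], grp[prev]] <- (L - h) / L
    }
  }
  if (length(unique(lens)) > 1) {
    for (j in seq(2, n)) {
      other <- which(lens[seq_len(j - 1)] != lens[j])
      if (!length(other)) next
      m[other, j] <- m[j, other] <- alignment_identity_many(seqs[j],
                                                            seqs[other])
    }
  }
  m
}

#' LULU-style merging of erroneous daughter ASVs
#'
#' Removes ASVs that look like sequencing errors of a more abundant
#' "parent": high sequence identity, occurrence restricted to the parent's
#' sites, and consistently lower abundance. Candidates are processed in
#' increasing total abundance (ties by id); each is merged into the most
#' abundant qualifying parent with
#' identity >= `lulu_min_match`, co-occurrence (fraction of the daughter's
#' sites where the parent also occurs) >= `lulu_cooccur`, and parent /
#' daughter site-level abundance ratio >= `lulu_min_ratio` at every shared
#' site. Merged counts are added to the parent, so later candidates see
#' updated abundances; the grand total is conserved.
#'
#' @param table An [asv_table()].
#' @param identity Optional precomputed symmetric identity matrix; computed
#'   with [pairwise_identity()] when `NULL`.
#' @param cfg A [run_config()].
#' @return The curated [asv_table()].
#' @export
lulu_curate <- function(table, identity = NULL, cfg = run_config()) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(identity)) identity <- pairwise_identity(table)
  ids <- rownames(table$counts)
  stopifnot(all(ids %in% rownames(identity)))
  counts <- table$counts
  site_of <- table_site_of(table)
  site_counts <- t(rowsum(t(counts), group = site_of, reorder = TRUE))
  alive <- setNames(rep(TRUE, length(ids)), ids)
  ord <- order(rowSums(counts), ids)   # least abundant first
  for (d in ids[ord]) {
    if (!alive[[d]]) next
    d_tot <- sum(counts[d, ])
    d_sites <- which(site_counts[d, ] > 0)
    if (length(d_sites) == 0 || d_tot == 0) next
    cand <- ids[alive & ids != d]
    cand <- cand[rowSums(counts[cand, , drop = FALSE]) > d_tot]
    cand <- cand[identity[d, cand] >= cfg$lulu_min_match]
    if (!length(cand)) next
    ok <- vapply(cand, function(p) {
      p_sites <- which(site_counts[p, ] > 0)
      cooccur <- length(intersect(d_sites, p_sites)) / length(d_sites)
      if (cooccur < cfg$lulu_cooccur) return(FALSE)
      shared <- intersect(d_sites, p_sites)
      all(site_counts[p, shared] / site_counts[d, shared] >= cfg$lulu_min_ratio)
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand)) next
    parent <- cand[order(-rowSums(counts[cand, , drop = FALSE]), cand)][1]
    counts[parent, ] <- counts[parent, ] + counts[d, ]
    site_counts[parent, ] <- site_counts[parent, ] + site_counts[d, ]
    alive[[d]] <- FALSE
  }
  keep <- ids[alive]
  asv_table(counts[keep, , drop = FALSE],
            sequences = if (!is.null(table$sequences)) table$sequences[keep])
}

#' Collapse replicates into a curated incidence table
#'
#' An ASV is scored present at a site only when it was detected (reads > 0)
#' in at least two of that site's replicates.
#'
#' @param table An [asv_table()] whose columns carry `<site>_r<k>` names;
#'   every site needs at least two replicates.
#' @return An integer site x ASV incidence matrix with values in `{0, 1}`.
#' @export
replicate_filter <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  site_of <- table_site_of(table)
  n_rep <- table(site_of)
  if (any(n_rep < 2)) {
    stop("replicate rule needs >= 2 replicates per site; offending site(s): ",
         paste(names(n_rep)[n_rep < 2], collapse = ", "), call. = FALSE)
  }
  detections <- t(rowsum(t(table$counts > 0) + 0L, group = site_of,
                         reorder = TRUE))
  inc <- t((detections >= 2L) + 0L)    # site x ASV
  storage.mode(inc) <- "integer"
  inc
}

#' Run the full curation cascade
#'
#' [dereplicate()] (if raw records are given) -> [cluster_d1()] ->
#' [filter_asvs()] -> [lulu_curate()] -> [replicate_filter()].
#'
#' @param table An [asv_table()] of dereplicated per-replicate counts.
#' @param is_fish Named logical vector by ASV id (see [filter_asvs()]).
#' @param cfg A [run_config()].
#' @return List with the curated `table` and the `incidence` matrix.
#' @export
curate <- function(table, is_fish, cfg = run_config()) {
  clustered <- cluster_d1(table)
  filtered <- filter_asvs(clustered, is_fish, cfg)
  curated <- lulu_curate(filtered, cfg = cfg)
  list(table = curated, incidence = replicate_filter(curated))
}
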