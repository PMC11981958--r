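#' Construct an ASV table
#'
#' The central container for curation: an integer matrix of read counts with
#' one row per ASV and one column per site-replicate sample, plus the ASV
#' sequences. Column names must follow the `<site>_r<k>` dialect, e.g.
#' `Y01_r1`; the site and replicate structure is always parsed from names,
#' never inferred from column order.
#'
#' @param counts Integer matrix, ASVs x samples, with `<site>_r<k>` column
#'   names and ASV ids as row names.
#' @param sequences Optional named character vector mapping ASV id to its
#'   sequence; when present it must cover every row.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("asv_table counts need unique ASV row names", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("asv_table counts need sample column names", call. = FALSE)
  }
  bad_col <- !grepl("^.+_r[0-9]+$", colnames(counts))
  if (any(bad_col)) {
    stop("sample columns must be named <site>_r<k>; offending: ",
         paste(colnames(counts)[bad_col], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(counts))) counts[is.na(counts)] <- 0L
  if (any(counts < 0) || any(counts != round(counts))) {
    idx <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers; offending cell row '",
         rownames(counts)[idx[1]], "', column '", colnames(counts)[idx[2]],
         "'", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(sequences)) {
    miss <- setdiff(rownames(counts), names(sequences))
    if (length(miss)) {
      stop("sequences missing for ASVs: ", paste(head(miss, 3), collapse = ", "),
           call. = FALSE)
    }
    sequences <- sequences[rownames(counts)]
  }
  structure(list(counts = counts, sequences = sequences), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV table:", nrow(x$counts), "ASVs x", ncol(x$counts), "samples (",
      length(table_sites(x)), "sites ),", sum(x$counts), "reads\n")
  invisible(x)
}

#' Sites and replicates of an ASV table
#'
#' @param table An [asv_table()].
#' @return `table_sites()`: character vector of unique site names.
#'   `table_site_of()`: the site of each sample column.
#' @export
table_sites <- function(table) unique(table_site_of(table))

#' @rdname table_sites
#' @export
table_site_of <- function(table) sub("_r[0-9]+$", "", colnames(table$counts))

#' Total reads and relative abundance per ASV
#'
#' @param table An [asv_table()].
#' @return `total_reads()`: named integer vector. `asv_freq()`: named
#'   numeric vector summing to 1 (relative to the table's grand total).
#' @export
total_reads <- function(table) rowSums(table$counts)

#' @rdname total_reads
#' @export
asv_freq <- function(table) {
  tot <- total_reads(table)
  tot / sum(tot)
}

#' Read a per-replicate ASV read-count table
#'
#' Expects a TSV whose first column is `asv_id` and whose remaining columns
#' are `<site>_r<k>` sample counts. Blank cells are read as 0.
#'
#' @param path Path to the TSV.
#' @param sequences Optional named sequence vector passed to [asv_table()].
#' @return An [asv_table()].
#' @export
read_count_table <- function(path, sequences = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "asv_id") {
    stop("count table must have an 'asv_id' first column then sample columns",
         call. = FALSE)
  }
  if (anyDuplicated(df$asv_id)) {
    stop("duplicated asv_id in ", path, ": '",
         df$asv_id[duplicated(df$asv_id)][1], "'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$asv_id
  suppressWarnings(storage.mode(m) <- "numeric")
  if (any(is.nan(m))) stop("non-numeric count in ", path, call. = FALSE)
  asv_table(m, sequences = sequences)
}

#' Write an ASV count or incidence table to TSV
#'
#' @param table An [asv_table()] or a numeric matrix with row and column
#'   names (e.g. a site x ASV incidence matrix).
#' @param path Output TSV path.
#' @param id_col Name of the first (row-id) column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_col = "asv_id") {
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                       id_col), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic keyed TSV (traits, covariates, lineage, facets)
#'
#' Thin wrapper around [utils::read.delim] that checks the presence and
#' uniqueness of a key column.
#'
#' @param path Path to the TSV.
#' @param key Name of the key column that must exist and be unique.
#' @return A data frame.
#' @export
read_keyed_tsv <- function(path, key) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!key %in% names(df)) {
    stop(path, " lacks required column '", key, "'", call. = FALSE)
  }
  if (anyDuplicated(df[[key]])) {
    stop(path, " has duplicated ", key, " values", call. = FALSE)
  }
  df
}
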