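#' Read a FASTA file of ASV or reference sequences
#'
#' Parses a (possibly multi-line) FASTA file into a data frame of sequence
#' records. Lowercase bases are normalised to uppercase and the alphabet is
#' validated against the IUPAC nucleotide code via [Biostrings::DNAStringSet].
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (header up to the first
#'   whitespace), `seq` (uppercase sequence) and `length` (bp), in file
#'   order. An empty file yields a zero-row data frame.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "acg", "tn"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0]
  if (length(lines) == 0) {
    return(data.frame(id = character(), seq = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("FASTA parse error at line 1: expected a '>' header, got: ",
         substr(lines[1], 1, 30), call. = FALSE)
  }
  hdr_idx <- which(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr_idx]))
  if (any(ids == "")) {
    bad <- hdr_idx[which(ids == "")[1]]
    stop("FASTA parse error at line ", bad, ": empty header", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicated id '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste0(lines[grp == i & !is_hdr], collapse = "")
  }, character(1))
  if (any(seqs == "")) {
    bad <- hdr_idx[which(seqs == "")[1]]
    stop("FASTA parse error at line ", bad, ": record '",
         ids[which(seqs == "")[1]], "' has an empty sequence", call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  # alphabet validation (IUPAC codes incl. ambiguity letters and '-')
  tryCatch(Biostrings::DNAStringSet(seqs),
           error = function(e) stop("FASTA parse error: ", conditionMessage(e),
                                    call. = FALSE))
  data.frame(id = ids, seq = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data frame with
#'   `id` and `seq` columns as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("write_fasta() needs uniquely named sequences", call. = FALSE)
  }
  dss <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}
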