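#' Default run configuration
#'
#' One flat list of every named cutoff the pipeline uses. Defaults are the
#' workflow's published values: the ASV filter cascade (minimum 10 reads,
#' 160--200 bp, relative abundance >= 0.001), the in-silico PCR window
#' (150--220 bp, at most 3 primer mismatches), the identity bands of the
#' hierarchical taxonomy (species >= 0.98, genus >= 0.96, family >= 0.90,
#' order below), LULU curation parameters (minimum match 0.84, abundance
#' ratio 1, co-occurrence 0.95), 8 Moran distance classes with 999
#' permutations, and 100 permutations for the PLS path model.
#'
#' @param seed Integer RNG seed; always recorded in output metadata.
#' @param ... Named overrides of any default; unknown names warn and are
#'   kept (so stage-specific extras can ride along).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    min_reads = 10L,
    min_len = 160L,
    max_len = 200L,
    min_freq = 0.001,
    lulu_min_match = 0.84,
    lulu_min_ratio = 1,
    lulu_cooccur = 0.95,
    id_species = 0.98,
    id_genus = 0.96,
    id_family = 0.90,
    pcr_min_len = 150L,
    pcr_max_len = 220L,
    pcr_max_mismatch = 3L,
    moran_classes = 8L,
    moran_n_perm = 999L,
    sem_n_perm = 100L,
    sem_tol = 1e-6,
    sem_max_iter = 300L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("run_config() overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      warning("unknown config keys: ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML or JSON
#'
#' Missing keys take the defaults of [run_config()]; unknown keys warn.
#'
#' @param path Path to a flat YAML or JSON document.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) raw$seed <- 1L
  do.call(run_config, raw)
}

#' Emit a structured log line
#'
#' Writes `stage | seed | message` to stderr so result tables stay clean.
#' @param stage Pipeline stage name.
#' @param seed Seed in effect.
#' @param ... Message parts, pasted.
#' @return Invisibly, the line.
#' @export
log_stage <- function(stage, seed, ...) {
  line <- sprintf("[%s] seed=%s %s", stage, seed, paste0(..., collapse = ""))
  message(line)
  invisible(line)
}
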