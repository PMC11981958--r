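#' Default catalogue of unitless morphological ratios
#'
#' Nine ratios of the eleven raw side-view measurements (body length Bl,
#' body depth Bd, head depth Hd, caudal peduncle depth CPd, caudal fin
#' depth CFd, eye diameter Ed, eye height Eh, oral gape position Om,
#' maxillary jaw length Jl, pectoral fin length PFl, pectoral fin position
#' PFp), describing feeding and locomotion: body elongation (Bl/Bd),
#' caudal-propulsion throttling (CFd/CPd), eye size and position, oral gape
#' position, jaw length, head depth, and pectoral fin size and position.
#'
#' @return Data frame with columns `ratio`, `num`, `den`.
#' @export
default_trait_catalogue <- function() {
  data.frame(
    ratio = c("Bl.Bd", "CFd.CPd", "Ed.Hd", "Eh.Bd", "Om.Bd", "Jl.Hd",
              "Hd.Bd", "PFl.Bl", "PFp.Bd"),
    num = c("Bl", "CFd", "Ed", "Eh", "Om", "Jl", "Hd", "PFl", "PFp"),
    den = c("Bd", "CPd", "Hd", "Bd", "Bd", "Hd", "Bd", "Bl", "Bd"),
    stringsAsFactors = FALSE)
}

#' Convert raw morphological measurements to unitless ratios
#'
#' Ratios are invariant to uniform rescaling of the source image, so
#' measurements may be in pixels or any common unit. A zero or missing
#' denominator yields an explicit `NA` to be handled by [impute_traits()].
#'
#' @param raw Data frame with an `asv_id` column and one column per raw
#'   measurement named as in [default_trait_catalogue()].
#' @param catalogue Ratio catalogue (data frame `ratio`, `num`, `den`).
#' @return Data frame: `asv_id` plus one column per ratio.
#' @export
trait_ratios <- function(raw, catalogue = default_trait_catalogue()) {
  stopifnot("asv_id" %in% names(raw))
  need <- unique(c(catalogue$num, catalogue$den))
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("raw trait table lacks measurement(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(asv_id = raw$asv_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(catalogue))) {
    den <- raw[[catalogue$den[i]]]
    val <- raw[[catalogue$num[i]]] / den
    val[!is.finite(val)] <- NA_real_
    out[[catalogue$ratio[i]]] <- val
  }
  out
}

#' Impute missing trait ratios by nearest taxonomic group mean
#'
#' Each missing cell is filled with the mean of that ratio over the ASV's
#' genus; if no genus mate has a value, the family mean, then the order
#' mean, then the global column mean.
#'
#' @param traits Data frame from [trait_ratios()] (may contain `NA`).
#' @param lineage Data frame with `asv_id`, `genus`, `family`, `order`.
#' @return The completed trait data frame (no `NA` left).
#' @export
impute_traits <- function(traits, lineage) {
  stopifnot("asv_id" %in% names(traits))
  lin <- lineage[match(traits$asv_id, lineage$asv_id), ]
  ratio_cols <- setdiff(names(traits), "asv_id")
  for (col in ratio_cols) {
    v <- traits[[col]]
    if (all(is.na(v))) {
      stop("trait column '", col, "' has no observed value to impute from",
           call. = FALSE)
    }
    for (i in which(is.na(v))) {
      filled <- NA_real_
      for (rank in c("genus", "family", "order")) {
        grp <- !is.na(lin[[rank]]) & lin[[rank]] == lin[[rank]][i]
        pool <- v[grp & !is.na(v)]
        if (length(pool)) { filled <- mean(pool); break }
      }
      if (is.na(filled)) filled <- mean(v, na.rm = TRUE)
      traits[[col]][i] <- filled
    }
  }
  traits
}

#' Ordinate the trait space
#'
#' Scale-centres each ratio column and performs a principal coordinates
#' analysis on Euclidean distances (for Euclidean input this coincides with
#' a PCA eigendecomposition, which is how it is computed). Axes are ordered
#' by decreasing eigenvalue; the retained dimensionality `k` is the
#' smallest number of axes reaching 95% cumulative variance, floored at 2.
#'
#' @param traits Complete trait data frame (`asv_id` + ratio columns).
#' @param var_target Cumulative variance threshold for axis retention.
#' @return List: `coords` (ASV x axes matrix, all axes), `var_explained`
#'   (fraction per axis), `k` (retained axes).
#' @export
functional_space <- function(traits, var_target = 0.95) {
  stopifnot("asv_id" %in% names(traits))
  m <- as.matrix(traits[, setdiff(names(traits), "asv_id"), drop = FALSE])
  rownames(m) <- traits$asv_id
  if (nrow(m) < 3) stop("functional_space() needs >= 3 ASVs", call. = FALSE)
  if (anyNA(m)) stop("trait matrix has missing values; impute first",
                     call. = FALSE)
  sds <- apply(m, 2, sd)
  if (all(sds == 0)) stop("trait matrix has rank 0 after centering",
                          call. = FALSE)
  z <- scale(m[, sds > 0, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]
  ve <- ev / sum(ev)
  k <- max(2L, which(cumsum(ve) >= var_target)[1])
  k <- min(k, length(ve))
  list(coords = pc$x[, seq_along(ve), drop = FALSE], var_explained = ve, k = k)
}

#' Convex-hull functional richness per site
#'
#' The functional richness of a site is the volume of the convex hull of
#' its ASVs in the retained trait-space axes, divided by the hull volume of
#' the full ASV pool, so values lie in `[0, 1]` and the pool scores 1.
#' Sites with fewer than `k + 1` ASVs, or whose ASVs are affinely
#' degenerate in the `k` axes, get 0 with a warning.
#'
#' @param fspace Output of [functional_space()].
#' @param incidence Site x ASV 0/1 matrix (ASV columns must be a subset of
#'   the ordinated ASVs).
#' @return Named numeric vector of FD per site.
#' @export
functional_richness <- function(fspace, incidence) {
  k <- fspace$k
  coords <- fspace$coords[, seq_len(k), drop = FALSE]
  miss <- setdiff(colnames(incidence), rownames(coords))
  if (length(miss)) {
    stop("incidence has ASVs absent from the trait space: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  pool_vol <- chull_volume(coords)
  if (pool_vol <= 0) stop("ASV pool is degenerate in the retained axes",
                          call. = FALSE)
  fd <- setNames(numeric(nrow(incidence)), rownames(incidence))
  flat <- character()
  for (s in rownames(incidence)) {
    present <- colnames(incidence)[incidence[s, ] > 0]
    if (length(present) < k + 1) { flat <- c(flat, s); next }
    v <- chull_volume(coords[present, , drop = FALSE])
    if (v <= 0) { flat <- c(flat, s); next }
    fd[s] <- v / pool_vol
  }
  if (length(flat)) {
    warning("FD set to 0 for site(s) with a degenerate hull: ",
            paste(flat, collapse = ", "), call. = FALSE)
  }
  fd
}
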