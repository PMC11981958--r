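#' Taxonomic richness per site
#'
#' The number of ASVs present (incidence > 0) at each site.
#'
#' @param incidence Site x ASV 0/1 matrix.
#' @return Named integer vector of richness per site.
#' @export
taxonomic_richness <- function(incidence) {
  r <- rowSums(incidence > 0)
  storage.mode(r) <- "integer"
  r
}

#' Chao2 incidence-based richness extrapolation
#'
#' From the incidence frequency counts Q1 (ASVs in exactly one sampling
#' unit) and Q2 (exactly two), the asymptotic richness is
#' `S_obs + ((T-1)/T) * Q1^2 / (2 Q2)` when `Q2 > 0`, and the bias-corrected
#' `S_obs + ((T-1)/T) * Q1 (Q1 - 1) / 2` otherwise; sample coverage is
#' reported as the fraction of the asymptote already observed.
#'
#' @param incidence Site x ASV 0/1 matrix with `T >= 2` sites.
#' @return List: `S_obs`, `S_asymptote`, `coverage_fraction`, `Q1`, `Q2`,
#'   `T`.
#' @export
incidence_extrapolation <- function(incidence) {
  if (is.null(dim(incidence)) || nrow(incidence) < 2) {
    stop("incidence_extrapolation() needs >= 2 sampling units", call. = FALSE)
  }
  occ <- colSums(incidence > 0)
  s_obs <- sum(occ > 0)
  if (s_obs == 0) stop("empty incidence table", call. = FALSE)
  q1 <- sum(occ == 1)
  q2 <- sum(occ == 2)
  t_units <- nrow(incidence)
  extra <- if (q2 > 0) {
    q1^2 / (2 * q2)
  } else {
    q1 * (q1 - 1) / 2
  }
  s_asym <- s_obs + (t_units - 1) / t_units * extra
  list(S_obs = s_obs, S_asymptote = s_asym,
       coverage_fraction = s_obs / s_asym, Q1 = q1, Q2 = q2, T = t_units)
}

#' Assemble the per-site facet table
#'
#' Convenience wrapper producing the site-level table of the three facets:
#' taxonomic richness (TD), convex-hull functional richness (FD) and mean
#' per-order nucleotide diversity (GD).
#'
#' @param incidence Site x ASV 0/1 matrix.
#' @param traits Complete trait ratio table (see [impute_traits()]).
#' @param sequences Named ASV sequence vector.
#' @param assignments Data frame with `asv_id` and `order`.
#' @return Data frame: `site`, `TD`, `FD`, `GD`.
#' @export
facet_table <- function(incidence, traits, sequences, assignments) {
  td <- taxonomic_richness(incidence)
  fs <- functional_space(traits)
  fd <- functional_richness(fs, incidence[, traits$asv_id, drop = FALSE])
  gd <- site_genetic_diversity(incidence, sequences, assignments)
  data.frame(site = rownames(incidence), TD = unname(td[rownames(incidence)]),
             FD = unname(fd[rownames(incidence)]),
             GD = unname(gd[rownames(incidence)]), stringsAsFactors = FALSE)
}
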