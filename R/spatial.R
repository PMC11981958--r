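#' Along-network distance from a site to the outlet
#'
#' Sum of reach lengths along the unique downstream path.
#'
#' @param net A [river_network()].
#' @param site Node name(s); defaults to every node.
#' @return Named numeric vector of distances (km).
#' @export
distance_to_outlet <- function(net, site = net$nodes) {
  bad <- setdiff(site, net$nodes)
  if (length(bad)) {
    stop("site(s) not on the network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nodes <- net$nodes
  pidx <- match(net$parent, nodes)
  elen <- unname(net$edge_length)
  memo <- rep(NA_real_, length(nodes))
  memo[match(net$outlet, nodes)] <- 0
  for (s in match(site, nodes)) {
    if (!is.na(memo[s])) next
    path <- integer()
    cur <- s
    while (is.na(memo[cur])) {      # walk downstream to a known node
      path <- c(path, cur)
      cur <- pidx[cur]
    }
    d <- memo[cur]
    for (p in rev(path)) {
      d <- d + elen[p]
      memo[p] <- d
    }
  }
  setNames(memo[match(site, nodes)], site)
}

#' Great-circle distance matrix in km
#' @noRd
haversine_km <- function(coords) {
  m <- geosphere::distm(as.matrix(coords[, c("lon", "lat")]),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(coords$site, coords$site)
  m
}

#' Moran spatial autocorrelogram with permutation inference
#'
#' Pairwise great-circle distances are binned into `n_classes` classes of
#' (approximately) equal pair counts; within each class, Moran's I is
#' computed with binary weights (1 for pairs falling in the class), and a
#' two-sided permutation p-value is obtained by permuting the values
#' `n_perm` times (add-one rule, centred on the null expectation
#' `-1/(n-1)`).
#'
#' @param values Named per-site numeric vector (non-constant).
#' @param coords Data frame with `site`, `lat`, `lon` covering the values.
#' @param n_classes Number of distance classes.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @return Data frame (`class`, `lower`, `upper`, `midpoint`, `n_pairs`,
#'   `I`, `p`) with attribute `first_significant`: the midpoint of the
#'   nearest class with `p < 0.05`, or `NA`.
#' @export
moran_correlogram <- function(values, coords, n_classes = 8L, n_perm = 999L,
                              seed = 1L) {
  sites <- names(values)
  if (length(sites) < 8) stop("need >= 8 sites", call. = FALSE)
  if (sd(values) == 0) stop("values are constant (zero variance)",
                            call. = FALSE)
  coords <- coords[match(sites, coords$site), ]
  dm <- haversine_km(coords)
  n <- length(values)
  pair_d <- dm[upper.tri(dm)]
  breaks <- quantile(pair_d, probs = seq(0, 1, length.out = n_classes + 1))
  breaks[1] <- breaks[1] - 1e-9
  cls <- cut(dm, breaks = breaks, labels = FALSE)
  cls[is.na(cls)] <- 0L
  dim(cls) <- dim(dm)
  diag(cls) <- 0L
  moran_i <- function(z, w) {
    s_w <- sum(w)
    (n / s_w) * sum(w * outer(z, z)) / sum(z^2)
  }
  null_mean <- -1 / (n - 1)
  set.seed(seed)
  perms <- replicate(n_perm, sample(values))
  out <- lapply(seq_len(n_classes), function(k) {
    w <- (cls == k) + 0
    z <- values - mean(values)
    i_obs <- moran_i(z, w)
    i_perm <- apply(perms, 2, function(v) moran_i(v - mean(v), w))
    p <- (1 + sum(abs(i_perm - null_mean) >= abs(i_obs - null_mean))) /
      (n_perm + 1)
    data.frame(class = k, lower = breaks[k], upper = breaks[k + 1],
               midpoint = (breaks[k] + breaks[k + 1]) / 2,
               n_pairs = sum(w) / 2, I = i_obs, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  sig <- out$midpoint[out$p < 0.05]
  attr(out, "first_significant") <- if (length(sig)) min(sig) else NA_real_
  out
}

#' Distance-weighted autocovariate
#'
#' For each site, the weighted mean of the response at neighbouring sites
#' within `radius_km`, with inverse-distance (default) or equal weights.
#' Sites without a neighbour inside the radius get 0 with a warning.
#'
#' @param values Named per-site numeric vector.
#' @param coords Data frame with `site`, `lat`, `lon`.
#' @param radius_km Neighbourhood radius (> 0).
#' @param weighting `"inverse_distance"` or `"equal"`.
#' @return Named numeric vector of autocovariate values.
#' @export
autocovariate <- function(values, coords, radius_km,
                          weighting = c("inverse_distance", "equal")) {
  weighting <- match.arg(weighting)
  if (radius_km <= 0) stop("radius_km must be > 0", call. = FALSE)
  sites <- names(values)
  coords <- coords[match(sites, coords$site), ]
  dm <- haversine_km(coords)
  out <- setNames(numeric(length(sites)), sites)
  isolated <- character()
  for (i in seq_along(sites)) {
    nb <- which(dm[i, ] > 0 & dm[i, ] <= radius_km)
    if (!length(nb)) { isolated <- c(isolated, sites[i]); next }
    w <- if (weighting == "inverse_distance") 1 / dm[i, nb] else rep(1, length(nb))
    out[i] <- sum(w * values[nb]) / sum(w)
  }
  if (length(isolated)) {
    warning("no neighbour within ", radius_km, " km for site(s): ",
            paste(isolated, collapse = ", "), "; autocovariate set to 0",
            call. = FALSE)
  }
  out
}

#' Residual spatial covariate (AutoCor)
#'
#' Residuals of the ordinary least squares fit of the response on its
#' autocovariate; by construction they are orthogonal to the autocovariate
#' and sum to zero, and serve as an independent spatial term in downstream
#' models.
#'
#' @param auto Autocovariate vector from [autocovariate()].
#' @param response Matching per-site response vector.
#' @return Named numeric vector of residuals. With a zero-variance
#'   autocovariate the centred response is returned with a warning.
#' @export
autocor_covariate <- function(auto, response) {
  stopifnot(length(auto) == length(response))
  if (sd(auto) == 0) {
    warning("autocovariate has zero variance; returning centred response",
            call. = FALSE)
    return(setNames(response - mean(response), names(response)))
  }
  setNames(unname(residuals(lm(response ~ auto))), names(response))
}

#' One-call spatial covariate construction
#'
#' Runs the correlogram, takes the nearest significant distance as the
#' autocovariate radius (falling back to the first class upper bound when
#' no class is significant), builds the distance-weighted autocovariate
#' and the AutoCor residual covariate.
#'
#' @inheritParams moran_correlogram
#' @return List: `correlogram`, `radius_km`, `auto`, `AutoCor`.
#' @export
spatial_covariates <- function(values, coords, n_classes = 8L, n_perm = 999L,
                               seed = 1L) {
  cg <- moran_correlogram(values, coords, n_classes, n_perm, seed)
  radius <- attr(cg, "first_significant")
  if (is.na(radius)) radius <- cg$upper[1]
  auto <- suppressWarnings(autocovariate(values, coords, radius))
  list(correlogram = cg, radius_km = radius, auto = auto,
       AutoCor = autocor_covariate(auto, values))
}
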