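# Small fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

# an asv_table from a named list of per-sample counts
make_table <- function(counts, sequences = NULL) {
  m <- do.call(rbind, counts)
  rownames(m) <- names(counts)
  asv_table(m, sequences = sequences)
}

# lat/lon frame for sites on a line, spaced `step_km` apart going north
line_coords <- function(sites, step_km = 10) {
  data.frame(site = sites,
             lat = 23 + (seq_along(sites) - 1) * step_km / 111.3195,
             lon = 102, stringsAsFactors = FALSE)
}

# random DNA string
rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# mutate exactly k positions of a sequence
mutate_k <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste0(x, collapse = "")
}

# Monte-Carlo convex hull volume: rejection sampling in the bounding
# box. Membership is tested independently of the package's hull code:
# 2-D by a point-in-convex-polygon sign test, 3-D by Caratheodory --
# a point lies in the hull iff it lies in some tetrahedron spanned by
# four of the input points (barycentric-coordinate check, vectorised
# over the Monte-Carlo sample).
mc_hull_volume <- function(pts, n_mc = 2e5, seed = 1) {
  set.seed(seed)
  d <- ncol(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  box <- prod(hi - lo)
  u <- matrix(runif(n_mc * d), n_mc, d)
  samp <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  if (d == 2) {
    hull_idx <- grDevices::chull(pts)
    poly <- pts[hull_idx, , drop = FALSE]
    inside <- point_in_poly(samp, poly)
  } else {
    inside <- rep(FALSE, n_mc)
    combs <- combn(nrow(pts), 4)
    for (k in seq_len(ncol(combs))) {
      v <- pts[combs[, k], , drop = FALSE]
      m <- t(v[2:4, , drop = FALSE]) - v[1, ]   # 3 x 3 edge matrix
      if (abs(det(m)) < 1e-12) next
      bc <- t(solve(m, t(samp) - v[1, ]))       # barycentric coords
      inside <- inside | (bc[, 1] >= -1e-12 & bc[, 2] >= -1e-12 &
                            bc[, 3] >= -1e-12 &
                            rowSums(bc) <= 1 + 1e-12)
      if (all(inside)) break
    }
  }
  box * mean(inside)
}

# point-in-convex-polygon: all edge cross products share one sign
# (either orientation of the vertex ring)
point_in_poly <- function(samp, poly) {
  k <- nrow(poly)
  pos <- neg <- rep(TRUE, nrow(samp))
  for (i in seq_len(k)) {
    a <- poly[i, ]; b <- poly[if (i == k) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (samp[, 2] - a[2]) -
      (b[2] - a[2]) * (samp[, 1] - a[1])
    pos <- pos & cr >= -1e-12
    neg <- neg & cr <= 1e-12
  }
  pos | neg
}

# cached large synthetic study for the path-recovery checks
.acc_cache <- new.env(parent = emptyenv())
sem_recovery_fit <- function(seed = 97, n = 5000L) {
  key <- paste("fit", seed, n, sep = "_")
  if (!exists(key, envir = .acc_cache)) {
    cfg <- sim_config(seed = seed, n_sites = n)
    cov <- generate_covariates(generate_network(cfg), cfg)
    fac <- generate_facets(cov, cfg)
    dat <- cbind(cov$covariates[, c("elevation", "footprint", "TP", "TN",
                                    "BOD5", "TOC")],
                 fac$facets[, c("TD", "FD", "GD")])
    fit <- fit_plspm(dat, biodiversity_path_model())
    assign(key, list(cfg = cfg, fit = fit), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}
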