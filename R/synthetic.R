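#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: 33 sampling
#' sites on a dendritic network with roughly two thirds of sites on the
#' mainstem, reach lengths of 5--30 km, an elevation gradient exceeding
#' 1000 m rising upstream, a human-footprint hump peaking in the middle
#' reaches, six structural path coefficients (elevation -> footprint
#' -0.5452; elevation -> water quality 0.4739; footprint -> water quality
#' 0.5485; elevation -> biodiversity -0.7056; footprint -> biodiversity
#' -0.1779; water quality -> biodiversity -0.0626) with disturbances
#' scaled so every endogenous latent has unit variance, indicator noise
#' sd 0.1, site richness spanning 13--79 ASVs, three field replicates, a
#' 232-ASV pool in 11 orders with the two dominant orders holding ~78% of
#' ASVs, and a 20% planted-error rate for curation benchmarks.
#'
#' @param seed Integer seed (mandatory; each generator stage derives its
#'   own stream from it).
#' @param n_sites Number of sampling sites (network nodes).
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed, n_sites = 33L, ...) {
  if (missing(seed)) stop("sim_config() requires a seed", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    n_sites = as.integer(n_sites),
    mainstem_frac = 2 / 3,
    edge_km = c(5, 30),
    elev_range = c(330, 1480),   # m, valley outlet to headwaters
    elev_sd = 40,                # m, local relief noise
    footprint_hump = 0.5,        # weight of the mid-basin footprint hump
    footprint_scale = c(20, 8),  # mean, sd of the unitless footprint index
    coefs = c(ef = -0.5452, ew = 0.4739, fw = 0.5485,
              eb = -0.7056, fb = -0.1779, wb = -0.0626),
    indicator_sd = 0.1,          # formative indicator noise (latent units)
    facet_noise_sd = 0.1,        # facet noise before monotone mapping
    richness_range = c(13L, 79L),
    fd_range = c(0.049, 0.793),
    gd_range = c(0.005, 0.087),
    n_replicates = 3L,
    p_det = 0.95,                # per-replicate detection probability
    error_rate = 0.2,            # fraction of ASVs spawning a daughter
    n_pool = 232L,
    order_counts = c(Cypriniformes = 133L, Perciformes = 49L,
                     Siluriformes = 13L, Gobiiformes = 9L,
                     Cyprinodontiformes = 7L, Anabantiformes = 6L,
                     Synbranchiformes = 5L, Beloniformes = 4L,
                     Salmoniformes = 3L, Anguilliformes = 2L,
                     Clupeiformes = 1L),
    order_pi = 0.06,             # target within-order nucleotide diversity
    seq_len = 170L,
    reads_per_presence = 1000,   # expected reads per site occurrence
    min_true_distance = 5L       # Hamming separation between true ASVs
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      warning("unknown sim_config keys: ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg$order_counts <- round(cfg$order_counts / sum(cfg$order_counts) *
                              cfg$n_pool)
  cfg$order_counts[1] <- cfg$order_counts[1] +
    (cfg$n_pool - sum(cfg$order_counts))
  structure(cfg, class = c("sim_config", "list"))
}

#' Generate a dendritic river network with planar coordinates
#'
#' A random bifurcating tree directed toward one outlet. About
#' `mainstem_frac` of the sites form a single root-to-leaf mainstem path
#' (`Type = 1`, names `Y..`), the rest hang off it as tributaries
#' (`Type = 0`, names `T..`). Reach lengths are uniform on `edge_km`;
#' coordinates are laid out in the plane so each reach's straight-line
#' length equals its channel length, then mapped to lat/lon.
#'
#' @param cfg A [sim_config()].
#' @return A [river_network()] whose `coords` carry `site`, `lat`, `lon`,
#'   `x_km`, `y_km`, `Type`.
#' @export
generate_network <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_sites
  stopifnot(n >= 3)
  n_main <- max(2L, round(cfg$mainstem_frac * n))
  main <- sprintf("Y%02d", seq_len(n_main))      # Y01 = outlet
  trib <- if (n > n_main) sprintf("T%02d", seq_len(n - n_main)) else character()
  child <- character(); parent <- character()
  if (n_main > 1) {
    child <- main[-1]; parent <- main[-n_main]
  }
  for (t in seq_along(trib)) {
    attach_to <- sample(c(main[-1], trib[seq_len(t - 1)]), 1)
    child <- c(child, trib[t]); parent <- c(parent, attach_to)
  }
  length_km <- runif(length(child), cfg$edge_km[1], cfg$edge_km[2])
  # planar layout: children placed one reach away from their parent
  pos <- matrix(0, n, 2, dimnames = list(c(main, trib), c("x", "y")))
  ang <- setNames(rep(pi / 2, n), c(main, trib))
  par_of <- setNames(parent, child)
  len_of <- setNames(length_km, child)
  placed <- main[1]
  todo <- child
  while (length(todo)) {
    ready <- todo[par_of[todo] %in% placed]
    for (ch in ready) {
      p <- par_of[[ch]]
      a <- if (startsWith(ch, "Y")) {
        ang[[p]] + runif(1, -0.35, 0.35)
      } else {
        ang[[p]] + sample(c(-1, 1), 1) * runif(1, 0.7, 1.3)
      }
      pos[ch, ] <- pos[p, ] + len_of[[ch]] * c(cos(a), sin(a))
      ang[[ch]] <- a
      placed <- c(placed, ch)
    }
    todo <- setdiff(todo, ready)
  }
  lat0 <- 23; lon0 <- 102
  coords <- data.frame(
    node = rownames(pos), site = rownames(pos),
    x_km = pos[, 1], y_km = pos[, 2],
    lat = lat0 + pos[, 2] / 111.32,
    lon = lon0 + pos[, 1] / (111.32 * cos(lat0 * pi / 180)),
    Type = as.integer(startsWith(rownames(pos), "Y")),
    stringsAsFactors = FALSE)
  river_network(child, parent, length_km, coords = coords)
}

#' Theoretical covariance of the exogenous + upstream latents
#' @noRd
latent_sigma <- function(co) {
  s_ef <- co[["ef"]]
  s_ew <- co[["ew"]] + co[["fw"]] * s_ef
  s_fw <- co[["fw"]] + co[["ew"]] * s_ef
  matrix(c(1, s_ef, s_ew,
           s_ef, 1, s_fw,
           s_ew, s_fw, 1), 3, 3,
         dimnames = rep(list(c("e", "f", "w")), 2))
}

#' Generate site covariates from the network
#'
#' Elevation falls linearly with distance to the outlet (plus local
#' relief noise); the standardized footprint is the structural
#' `ef` path from elevation plus a mid-basin hump and noise, scaled back
#' to a positive footprint index; the latent water-quality pressure
#' follows its structural equation with a disturbance sized for unit
#' variance, and TP/TN/BOD5/TOC are the latent plus indicator noise mapped
#' to positive mg/L scales.
#'
#' @param net A network from [generate_network()].
#' @param cfg A [sim_config()].
#' @return List: `covariates` (site, lat, lon, dist_outlet, elevation,
#'   footprint, TP, TN, BOD5, TOC, Type) and `latents` (standardized
#'   elevation, footprint, water_quality).
#' @export
generate_covariates <- function(net, cfg) {
  set.seed(cfg$seed + 2L)
  co <- cfg$coefs
  sites <- net$coords$site
  d <- distance_to_outlet(net, sites)
  u <- d / max(d)
  elevation <- cfg$elev_range[1] +
    (cfg$elev_range[2] - cfg$elev_range[1]) * u +
    rnorm(length(u), 0, cfg$elev_sd)
  e_star <- as.numeric(scale(elevation))
  hump <- 4 * u * (1 - u)
  h_star <- as.numeric(scale(hump))
  c_h <- cfg$footprint_hump
  s1 <- sqrt(max(1 - co[["ef"]]^2 - c_h^2, 0.01))
  f_star <- co[["ef"]] * e_star + c_h * h_star + rnorm(length(u), 0, s1)
  footprint <- pmax(cfg$footprint_scale[1] +
                      cfg$footprint_scale[2] * f_star, 0)
  sig <- latent_sigma(co)
  v2 <- 1 - (co[["ew"]]^2 + co[["fw"]]^2 +
               2 * co[["ew"]] * co[["fw"]] * sig["e", "f"])
  if (v2 <= 0) stop("structural coefficients imply non-positive water-quality",
                    " disturbance variance", call. = FALSE)
  w_star <- co[["ew"]] * e_star + co[["fw"]] * f_star +
    rnorm(length(u), 0, sqrt(v2))
  wq_ind <- function(center, spread) {
    pmax(center + spread * (w_star + rnorm(length(u), 0, cfg$indicator_sd)), 0)
  }
  covariates <- data.frame(
    site = sites, lat = net$coords$lat, lon = net$coords$lon,
    dist_outlet = unname(d), elevation = elevation, footprint = footprint,
    TP = wq_ind(0.15, 0.05), TN = wq_ind(1.5, 0.5),
    BOD5 = wq_ind(3.0, 1.0), TOC = wq_ind(4.0, 1.2),
    Type = net$coords$Type, stringsAsFactors = FALSE)
  latents <- data.frame(site = sites, elevation = e_star, footprint = f_star,
                        water_quality = w_star, stringsAsFactors = FALSE)
  list(covariates = covariates, latents = latents)
}

#' Rank-preserving linear map of a latent onto an observed facet range
#' @noRd
linmap <- function(z, lo, hi) {
  if (max(z) == min(z)) return(rep((lo + hi) / 2, length(z)))
  lo + (hi - lo) * (z - min(z)) / (max(z) - min(z))
}

#' Generate the three biodiversity facets from the covariate latents
#'
#' The latent biodiversity follows its structural equation (paths from
#' elevation, footprint and water quality) with the disturbance scaled to
#' unit variance; observed facets are monotone rank-preserving rescalings
#' of noisy copies: TD to integer richness in `richness_range`, FD to
#' `fd_range`, and GD to `gd_range` with the sign inverted (genetic
#' diversity runs against the other two facets along the gradient).
#'
#' @param cov_bundle Output of [generate_covariates()].
#' @param cfg A [sim_config()].
#' @return List: `facets` (site, TD, FD, GD) and `latents` (the covariate
#'   latents plus `biodiversity`).
#' @export
generate_facets <- function(cov_bundle, cfg) {
  set.seed(cfg$seed + 3L)
  co <- cfg$coefs
  lat <- cov_bundle$latents
  beta <- c(co[["eb"]], co[["fb"]], co[["wb"]])
  sig <- latent_sigma(co)
  v3 <- 1 - as.numeric(t(beta) %*% sig %*% beta)
  if (v3 <= 0) stop("structural coefficients imply non-positive biodiversity",
                    " disturbance variance", call. = FALSE)
  n <- nrow(lat)
  b_star <- beta[1] * lat$elevation + beta[2] * lat$footprint +
    beta[3] * lat$water_quality + rnorm(n, 0, sqrt(v3))
  noisy <- function() b_star + rnorm(n, 0, cfg$facet_noise_sd)
  td <- as.integer(round(linmap(noisy(), cfg$richness_range[1],
                                cfg$richness_range[2])))
  fd <- linmap(noisy(), cfg$fd_range[1], cfg$fd_range[2])
  gd <- linmap(-noisy(), cfg$gd_range[1], cfg$gd_range[2])
  latents <- cov_bundle$latents
  latents$biodiversity <- b_star
  list(facets = data.frame(site = lat$site, TD = td, FD = fd, GD = gd,
                           stringsAsFactors = FALSE),
       latents = latents)
}

#' Per-position mutation rate giving a target pairwise diversity
#'
#' Two sequences independently mutated from an ancestor at per-position
#' rate q (uniform choice among the three other bases) differ at a
#' position with probability `2q(1-q) + (2/3)q^2`; this inverts that
#' relation.
#' @noRd
mutation_rate_for_pi <- function(target_pi) {
  (3 / 4) * (1 - sqrt(1 - (4 / 3) * target_pi))
}

#' sample() without the length-one surprise
#' @noRd
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Mutate `k` random positions of a sequence to different bases
#' @noRd
mutate_positions <- function(seq, k) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(bases, x[p]), 1)
  paste0(x, collapse = "")
}

#' Generate ASV tables, sequences, traits and lineage with known truth
#'
#' Builds a global pool of true ASVs assigned to orders in the configured
#' proportions; sequences evolve from a random per-order ancestor at a
#' per-position rate tuned so within-order nucleotide diversity matches
#' `order_pi`, with a minimum pairwise Hamming separation so that
#' single-nucleotide error daughters never bridge two true ASVs. Each
#' site receives its TD true ASVs (sampled with lognormal commonness
#' weights); reads per occurrence share a roughly equal per-ASV total
#' budget (lognormal jitter) so every true ASV clears the read and
#' relative-abundance filters; replicates thin detections at `p_det`.
#' A fraction `error_rate` of true ASVs spawns one erroneous daughter at
#' 2--8% of the parent's reads in a random subset of the parent's sites:
#' half at Hamming distance 1 (removed by [cluster_d1()]), half at 2--3
#' substitutions (removed by [lulu_curate()]). Raw morphological
#' measurements come from order-specific lognormals.
#'
#' @param facets Data frame with `site` and `TD` columns (e.g. from
#'   [generate_facets()]).
#' @param cfg A [sim_config()].
#' @return List: `table` (per-replicate [asv_table()] including planted
#'   daughters), `sequences`, `traits` (11 raw measurements per true ASV),
#'   `lineage` (asv_id, species, genus, family, order, native),
#'   `fish_orders`, and `truth`: `incidence` (site x realized true ASVs),
#'   `pool` (the realized true ASVs), `regional_pool` (including pool
#'   members never sampled at any site, which cannot appear in a read
#'   table), and the `daughters` map.
#' @export
generate_asv_data <- function(facets, cfg) {
  set.seed(cfg$seed + 4L)
  bases <- c("A", "C", "G", "T")
  orders <- rep(names(cfg$order_counts), cfg$order_counts)
  n_pool <- length(orders)
  ids <- sprintf("sp%03d", seq_len(n_pool))
  q <- mutation_rate_for_pi(cfg$order_pi)
  seqs <- character(n_pool)
  for (o in unique(orders)) {
    idx <- which(orders == o)
    ancestor <- paste0(sample(bases, cfg$seq_len, replace = TRUE),
                       collapse = "")
    done <- character()
    for (i in idx) {
      for (try in 1:60) {
        k <- rbinom(1, cfg$seq_len, q)
        cand <- if (k > 0) mutate_positions(ancestor, k) else ancestor
        if (!length(done) ||
            min(vapply(done, hamming, integer(1), a = cand)) >=
            cfg$min_true_distance) break
      }
      seqs[i] <- cand
      done <- c(done, cand)
    }
  }
  # synthetic lineage: ~3 families per order, ~2 genera per family
  fam <- paste0(substr(orders, 1, 4), "idae", (seq_len(n_pool) %% 3) + 1)
  gen <- paste0("Genus_", substr(orders, 1, 3), (seq_len(n_pool) %% 6) + 1)
  lineage <- data.frame(
    asv_id = ids, species = paste0("Species_", ids), genus = gen,
    family = fam, order = orders,
    native = seq_len(n_pool) %% 4 == 0, stringsAsFactors = FALSE)
  # occupancy: TD ASVs per site, commonness-weighted
  commonness <- rlnorm(n_pool, 0, 1)
  sites <- facets$site
  inc <- matrix(0L, length(sites), n_pool, dimnames = list(sites, ids))
  for (s in seq_along(sites)) {
    td <- min(facets$TD[s], n_pool)
    inc[s, sample(n_pool, td, prob = commonness)] <- 1L
  }
  # Genuine taxa have independent habitat preferences: whenever one true
  # ASV's occupancy is near-nested inside a same-order neighbour's, the
  # nested taxon gets an extra site outside the neighbour's range. This
  # occupancy signature is what separates real taxa from error daughters
  # (which, by construction, only ever occur inside their parent's range).
  for (round in 1:10) {
    changed <- FALSE
    for (o in unique(orders)) {
      idx <- which(orders == o & colSums(inc) > 0)
      if (length(idx) < 2) next
      for (a in idx) {
        a_sites <- which(inc[, a] > 0)
        for (b in idx) {
          if (a == b) next
          b_sites <- which(inc[, b] > 0)
          if (sum(a_sites %in% b_sites) / length(a_sites) < 0.95) next
          outside <- setdiff(seq_along(sites), b_sites)
          need <- ceiling(length(a_sites) * 0.051)
          outside <- setdiff(outside, a_sites)
          if (length(outside) >= need) {
            inc[sample_vec(outside, need), a] <- 1L
            a_sites <- which(inc[, a] > 0)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  present <- colSums(inc) > 0
  occ <- pmax(colSums(inc), 1)
  lambda <- cfg$reads_per_presence * nrow(inc) / (3 * occ) *
    rlnorm(n_pool, 0, 0.3)   # roughly equal per-ASV total read budgets
  # per-replicate counts for true ASVs
  reps <- cfg$n_replicates
  samples <- as.vector(t(outer(sites, seq_len(reps),
                               function(s, r) paste0(s, "_r", r))))
  counts <- matrix(0L, n_pool, length(samples),
                   dimnames = list(ids, samples))
  for (s in seq_along(sites)) {
    for (a in which(inc[s, ] > 0)) {
      det <- runif(reps) <= cfg$p_det
      if (cfg$p_det >= 1) det <- rep(TRUE, reps)
      for (r in which(det)) {
        counts[a, paste0(sites[s], "_r", r)] <-
          max(1L, as.integer(round(lambda[a] * rlnorm(1, 0, 0.3))))
      }
    }
  }
  # Fallback for taxa that could not get an outside site (the neighbour
  # spans nearly the whole basin): make the nested taxon locally dominant
  # (2x margin) at its strongest site, so its abundance pattern, like a
  # real taxon's and unlike an error's, is not uniformly below the
  # neighbour's.
  site_cols <- lapply(sites, function(s) which(startsWith(samples,
                                                          paste0(s, "_"))))
  site_reads <- function() {
    vapply(site_cols, function(cc) rowSums(counts[, cc, drop = FALSE]),
           numeric(n_pool))   # n_pool x n_sites
  }
  for (round in 1:10) {
    sr <- site_reads()
    occ_m <- sr > 0
    fixed_any <- FALSE
    for (o in unique(orders)) {
      idx <- which(orders == o & present)
      if (length(idx) < 2) next
      for (a in idx) {
        a_sites <- which(occ_m[a, ])
        if (!length(a_sites)) next
        for (b in idx) {
          if (a == b) next
          shared <- a_sites[occ_m[b, a_sites]]
          if (length(shared) / length(a_sites) < 0.95) next
          if (any(sr[a, shared] > sr[b, shared])) next
          # boost a at the site where it comes closest to b
          s_star <- shared[which.max(sr[a, shared] / sr[b, shared])]
          f <- 2 * sr[b, s_star] / max(sr[a, s_star], 1)
          if (f > 1e4) next   # give up rather than distort the table
          cc <- site_cols[[s_star]]
          counts[a, cc] <- as.integer(ceiling(counts[a, cc] * f))
          sr[a, ] <- vapply(site_cols, function(cc2) {
            sum(counts[a, cc2])
          }, numeric(1))
          fixed_any <- TRUE
        }
      }
    }
    if (!fixed_any) break
  }
  # planted erroneous daughters
  daughters <- list()
  d_counts <- list()
  d_seqs <- character()
  spawn <- which(present & runif(n_pool) < cfg$error_rate)
  for (a in spawn) {
    n_sub <- if (runif(1) < 0.5) 1L else sample(2:3, 1)
    for (try in 1:60) {
      d_seq <- mutate_positions(seqs[a], n_sub)
      ok_true <- min(vapply(seqs, function(s) {
        if (nchar(s) == nchar(d_seq)) hamming(d_seq, s) else 99L
      }, integer(1))[-a]) >= 2L
      ok_err <- !length(d_seqs) ||
        min(vapply(d_seqs, hamming, integer(1), a = d_seq)) >= 2L
      if (ok_true && ok_err && !d_seq %in% seqs) break
    }
    p_sites <- which(inc[, a] > 0)
    sub_sites <- sort(sample(p_sites, max(1, ceiling(length(p_sites) / 2))))
    frac <- runif(1, 0.02, 0.08)
    did <- sprintf("err%03d", length(daughters) + 1L)
    row <- setNames(integer(length(samples)), samples)
    for (s in sub_sites) {
      for (r in seq_len(reps)) {
        col <- paste0(sites[s], "_r", r)
        if (counts[a, col] > 0) {
          row[col] <- max(1L, as.integer(round(frac * counts[a, col])))
        }
      }
    }
    daughters[[did]] <- data.frame(
      daughter_id = did, parent_id = ids[a], n_sub = n_sub,
      stringsAsFactors = FALSE)
    d_counts[[did]] <- row
    d_seqs <- c(d_seqs, setNames(d_seq, did))
  }
  # regional-pool members never sampled at any site are unobservable and
  # do not appear in the read table (a dereplicated table has no all-zero
  # rows); the realized true set is what curation can be asked to recover
  all_counts <- counts[present, , drop = FALSE]
  if (length(d_counts)) {
    all_counts <- rbind(all_counts, do.call(rbind, d_counts))
  }
  all_seqs <- c(setNames(seqs, ids)[present], d_seqs)
  # raw morphological measurements: two latent morphological axes
  # (elongation-like and feeding-like) drive order- and ASV-level
  # variation, with a small residual -- so the trait-space ordination is
  # dominated by two axes, as it is for real fish side-view morphometry
  base_meas <- c(Bl = 100, Bd = 25, Hd = 20, CPd = 8, CFd = 18, Ed = 5,
                 Eh = 10, Om = 12, Jl = 10, PFl = 20, PFp = 12)
  n_ord <- length(unique(orders))
  load1 <- rnorm(length(base_meas), 0, 0.2)
  load2 <- rnorm(length(base_meas), 0, 0.15)
  u1 <- setNames(rnorm(n_ord), unique(orders))[orders] + rnorm(n_pool, 0, 0.5)
  u2 <- setNames(rnorm(n_ord), unique(orders))[orders] + rnorm(n_pool, 0, 0.5)
  traits <- data.frame(asv_id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(base_meas)) {
    m <- names(base_meas)[k]
    traits[[m]] <- base_meas[[m]] *
      exp(load1[k] * u1 + load2[k] * u2 + rnorm(n_pool, 0, 0.02))
  }
  list(table = asv_table(all_counts, sequences = all_seqs),
       sequences = all_seqs, traits = traits, lineage = lineage,
       fish_orders = unique(orders),
       truth = list(incidence = inc[, present, drop = FALSE],
                    pool = data.frame(asv_id = ids, order = orders,
                                      seq = seqs,
                                      stringsAsFactors = FALSE)[present, ],
                    regional_pool = data.frame(asv_id = ids, order = orders,
                                               seq = seqs,
                                               stringsAsFactors = FALSE),
                    daughters = if (length(daughters)) {
                      do.call(rbind, daughters)
                    } else {
                      data.frame(daughter_id = character(),
                                 parent_id = character(), n_sub = integer())
                    }))
}

#' Generate a complete synthetic study
#'
#' Network, covariates, facets and ASV data in one call, each stage on its
#' own seed stream derived from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `network`, `covariates`, `latents`, `facets`, `asv`.
#' @export
simulate_study <- function(cfg) {
  net <- generate_network(cfg)
  cov <- generate_covariates(net, cfg)
  fac <- generate_facets(cov, cfg)
  asv <- generate_asv_data(fac$facets, cfg)
  list(network = net, covariates = cov$covariates, latents = fac$latents,
       facets = fac$facets, asv = asv)
}

#' Indicator table for the path model from a synthetic study
#'
#' Binds the covariate and facet columns into the site x indicator table
#' [fit_plspm()] expects for [biodiversity_path_model()].
#'
#' @param study Output of [simulate_study()] (or a list with `covariates`
#'   and `facets`).
#' @return Data frame with elevation, footprint, TP, TN, BOD5, TOC, TD,
#'   FD, GD columns.
#' @export
sem_indicators <- function(study) {
  stopifnot(identical(study$covariates$site, study$facets$site))
  cbind(study$covariates[, c("elevation", "footprint", "TP", "TN", "BOD5",
                             "TOC")],
        study$facets[, c("TD", "FD", "GD")])
}
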