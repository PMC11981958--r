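test_that("taxonomic richness is the per-site presence count", {
  inc <- rbind(Y01 = c(1L, 1L, 0L), Y02 = c(0L, 0L, 0L), T01 = c(1L, 0L, 1L))
  colnames(inc) <- c("a", "b", "c")
  td <- taxonomic_richness(inc)
  expect_equal(td, c(Y01 = 2L, Y02 = 0L, T01 = 2L))
  expect_equal(sum(colSums(inc) > 0), 3L)
})

test_that("trait ratios are unitless and flag zero denominators", {
  raw <- data.frame(asv_id = c("a", "b"),
                    Bl = c(10, 20), Bd = c(2, 4), Hd = c(4, 8),
                    CPd = c(1.5, 3), CFd = c(3, 6), Ed = c(1, 2),
                    Eh = c(2, 4), Om = c(2, 4), Jl = c(2, 4),
                    PFl = c(4, 8), PFp = c(2, 4))
  tr <- trait_ratios(raw)
  expect_equal(tr$Bl.Bd, c(5, 5))
  expect_equal(tr$CFd.CPd, c(2, 2))
  # b is a uniformly x2 rescaled a: identical ratios throughout
  expect_equal(unlist(tr[1, -1]), unlist(tr[2, -1]))
  raw$Bd[1] <- 0
  expect_true(is.na(trait_ratios(raw)$Bl.Bd[1]))
})

test_that("imputation walks genus -> family -> order -> global means", {
  traits <- data.frame(asv_id = c("a", "b", "c", "d", "e"),
                       r1 = c(4, 6, NA, 10, NA))
  lineage <- data.frame(asv_id = c("a", "b", "c", "d", "e"),
                        genus = c("G1", "G1", "G1", "G2", "G3"),
                        family = c("F1", "F1", "F1", "F1", "F2"),
                        order = "O1", stringsAsFactors = FALSE)
  out <- impute_traits(traits, lineage)
  expect_equal(out$r1[3], 5)              # genus mates 4, 6
  # no genus or family mate: order mean over *observed* values only
  expect_equal(out$r1[5], mean(c(4, 6, 10)))
  full <- data.frame(asv_id = c("a", "b"), r1 = c(1, 2))
  expect_identical(impute_traits(full, lineage), full)
  empty <- data.frame(asv_id = c("a", "b"), r1 = c(NA_real_, NA_real_))
  expect_error(impute_traits(empty, lineage), "no observed value")
})

test_that("functional space equals a direct covariance eigendecomposition", {
  set.seed(61)
  m <- matrix(rnorm(30 * 9), 30, 9)
  traits <- data.frame(asv_id = sprintf("a%02d", 1:30), m)
  fs <- functional_space(traits)
  ev_oracle <- eigen(cov(scale(m)), symmetric = TRUE)$values
  ev_oracle <- ev_oracle[ev_oracle > 1e-12]
  expect_equal(fs$var_explained, ev_oracle / sum(ev_oracle), tolerance = 1e-8)
  expect_equal(fs$k, max(2L, which(cumsum(fs$var_explained) >= 0.95)[1]))
})

test_that("functional space handles degenerate and symmetric inputs", {
  # collinear points in 9-D: a single axis carries all variance
  v <- rnorm(9)
  line <- data.frame(asv_id = c("a", "b", "c", "d"),
                     t(vapply(1:4, function(i) i * v, numeric(9))))
  fs <- functional_space(line)
  expect_equal(fs$var_explained[1], 1, tolerance = 1e-8)
  # isotropic 2-D cloud: two near-equal fractions
  set.seed(62)
  iso <- data.frame(asv_id = sprintf("a%03d", 1:400),
                    x = rnorm(400), y = rnorm(400))
  fs2 <- functional_space(iso)
  expect_lt(abs(fs2$var_explained[1] - 0.5), 0.06)
  # rank-0 input errors
  flat <- data.frame(asv_id = c("a", "b", "c"), r1 = c(1, 1, 1))
  expect_error(functional_space(flat), "rank 0")
})

test_that("functional space is invariant to affine rescaling of one column", {
  set.seed(63)
  m <- matrix(rnorm(20 * 5), 20, 5)
  t1 <- data.frame(asv_id = sprintf("a%02d", 1:20), m)
  m2 <- m; m2[, 3] <- 100 * m2[, 3] + 7
  t2 <- data.frame(asv_id = t1$asv_id, m2)
  expect_equal(functional_space(t1)$var_explained,
               functional_space(t2)$var_explained, tolerance = 1e-8)
})

test_that("hull volumes are exact on known shapes", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  expect_equal(chull_volume(square), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(chull_volume(tri), 0.5)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(chull_volume(cube), 1, tolerance = 1e-10)
  simplex4 <- rbind(rep(0, 4), diag(4))     # 4-D simplex: 1/4!
  expect_equal(chull_volume(simplex4), 1 / 24, tolerance = 1e-10)
  # degenerate clouds have zero volume
  expect_equal(chull_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(chull_volume(matrix(rnorm(6), 2, 3)), 0)
})

test_that("functional richness normalizes by the pool hull", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1))
  fspace <- list(coords = coords, var_explained = c(0.6, 0.4), k = 2L)
  inc <- rbind(all = c(1L, 1L, 1L, 1L),
               tri = c(1L, 1L, 1L, 0L),
               two = c(1L, 1L, 0L, 0L))
  colnames(inc) <- rownames(coords)
  fd <- suppressWarnings(functional_richness(fspace, inc))
  expect_equal(unname(fd["all"]), 1)
  expect_equal(unname(fd["tri"]), 0.5)   # triangle / square
  expect_equal(unname(fd["two"]), 0)     # 2 points in 2-D: degenerate
  expect_warning(functional_richness(fspace, inc), "degenerate")
})

test_that("adding an ASV to a site never decreases functional richness", {
  set.seed(64)
  n <- 15
  coords <- matrix(rnorm(n * 2), n, 2,
                   dimnames = list(sprintf("a%02d", 1:n), NULL))
  fspace <- list(coords = coords, var_explained = c(0.5, 0.5), k = 2L)
  for (rep in 1:10) {
    base <- rbinom(n, 1, 0.5)
    grown <- base
    grown[sample(which(grown == 0), 1)] <- 1L
    inc <- rbind(s1 = base, s2 = grown)
    colnames(inc) <- rownames(coords)
    fd <- suppressWarnings(functional_richness(fspace, inc))
    expect_gte(fd[["s2"]], fd[["s1"]] - 1e-12)
  }
})

test_that("nucleotide diversity equals the exhaustive pairwise oracle", {
  expect_equal(nucleotide_diversity(c("AAAA", "AAAA")), 0)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT")), 0.25)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AATT")), 1 / 3)
  expect_true(is.na(nucleotide_diversity("AAAA")))
  expect_error(nucleotide_diversity(c("AAAA", "AAA")), "equal-length")

  pi_oracle <- function(seqs) {
    pairs <- combn(length(seqs), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      a <- strsplit(seqs[pairs[1, k]], "")[[1]]
      b <- strsplit(seqs[pairs[2, k]], "")[[1]]
      keep <- !(a == "-" & b == "-")
      sum(a[keep] != b[keep]) / sum(keep)
    }, numeric(1)))
  }
  set.seed(65)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    seqs <- replicate(n, rand_dna(40))
    expect_equal(nucleotide_diversity(seqs), pi_oracle(seqs))
  }
})

test_that("gap columns are handled per pair", {
  # gap-vs-gap positions drop out of the denominator; gap-vs-base differs
  seqs <- c("AC-A", "AC-T", "ACGA")
  # pair 1-2: L = 3, 1 diff -> 1/3 ; pair 1-3: L = 4, 1 diff (gap vs G)
  # -> 1/4 ; pair 2-3: gap vs G and A vs T -> 2/4
  expect_equal(nucleotide_diversity(seqs), mean(c(1 / 3, 1 / 4, 2 / 4)))
})

test_that("site genetic diversity averages per-order diversity, unweighted", {
  seqs <- c(a1 = "AAAAAAAAAA", a2 = "TAAAAAAAAA",   # order A: pi = 0.1
            b1 = "CCCCCCCCCC", b2 = "CCCCCCCCGG",   # order B: pi = 0.2
            c1 = "GGGGGGGGGG")                      # singleton order
  assignments <- data.frame(asv_id = names(seqs),
                            order = c("A", "A", "B", "B", "C"),
                            stringsAsFactors = FALSE)
  inc <- rbind(Y01 = c(1L, 1L, 1L, 1L, 1L),
               Y02 = c(1L, 1L, 0L, 0L, 0L),
               Y03 = c(1L, 0L, 0L, 0L, 1L))
  colnames(inc) <- names(seqs)
  gd <- site_genetic_diversity(inc, seqs, assignments)
  expect_equal(unname(gd["Y01"]), mean(c(0.1, 0.2)))
  expect_equal(unname(gd["Y02"]), 0.1)
  expect_true(is.na(gd[["Y03"]]))    # only singleton orders
})

test_that("Chao2 extrapolation follows the closed form", {
  # no uniques: the asymptote is the observed richness
  inc <- rbind(s1 = c(1L, 1L), s2 = c(1L, 1L), s3 = c(1L, 0L))
  colnames(inc) <- c("a", "b")
  out <- incidence_extrapolation(inc)
  expect_equal(out$S_asymptote, out$S_obs)
  expect_equal(out$coverage_fraction, 1)

  # worked example: S_obs = 10, Q1 = 4, Q2 = 2, T = 33
  m <- matrix(0L, 33, 10, dimnames = list(sprintf("s%02d", 1:33),
                                          sprintf("a%02d", 1:10)))
  for (j in 1:4) m[j, j] <- 1L                       # 4 uniques
  for (j in 5:6) m[c(2 * j, 2 * j + 1), j] <- 1L     # 2 duplicates
  for (j in 7:10) m[1:(j - 3), j] <- 1L              # the rest widespread
  out <- incidence_extrapolation(m)
  expect_equal(out$Q1, 4); expect_equal(out$Q2, 2)
  expect_equal(out$S_asymptote, 10 + (32 / 33) * 16 / 4, tolerance = 1e-12)
  expect_equal(out$S_asymptote, 13.8787879, tolerance = 1e-6)

  expect_error(incidence_extrapolation(matrix(0L, 2, 2)), "empty")
})

test_that("Chao2 coverage is bounded and saturates when the design is doubled", {
  # Coverage is not monotone under duplicating a single site (a species
  # seen exactly twice, once there, moves from Q2 to a higher count and
  # the asymptote can rise); the guaranteed behaviours are bounds and the
  # doubled-design limit, where no species can remain unique.
  set.seed(66)
  for (rep in 1:15) {
    m <- matrix(rbinom(6 * 8, 1, 0.35), 6, 8,
                dimnames = list(sprintf("s%d", 1:6), sprintf("a%d", 1:8)))
    if (sum(m) == 0) next
    base <- incidence_extrapolation(m)
    expect_gte(base$S_asymptote, base$S_obs)
    expect_gt(base$coverage_fraction, 0)
    expect_lte(base$coverage_fraction, 1)
    doubled <- rbind(m, m)
    rownames(doubled) <- sprintf("s%d", 1:12)
    out <- incidence_extrapolation(doubled)
    expect_equal(out$Q1, 0L)
    expect_equal(out$coverage_fraction, 1)
    expect_gte(out$coverage_fraction, base$coverage_fraction - 1e-12)
  }
})
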