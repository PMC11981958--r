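# standardized OLS path-analysis oracle for single-indicator blocks
ols_paths <- function(data, model) {
  z <- as.data.frame(scale(data))
  out <- list()
  for (l in model$latents) {
    preds <- model$latents[model$inner[, l]]
    if (!length(preds)) next
    cols <- vapply(preds, function(p) model$blocks[[p]], character(1))
    yc <- model$blocks[[l]]
    fit <- lm(z[[yc]] ~ ., data = z[, cols, drop = FALSE])
    out[[l]] <- setNames(unname(coef(fit))[-1], preds)
  }
  out
}

test_that("two single-indicator latents collapse to the standardized slope", {
  set.seed(91)
  x <- rnorm(80)
  dat <- data.frame(x = x, y = 0.8 * x)
  model <- path_model(blocks = list(X = "x", Y = "y"),
                      edges = rbind(c("X", "Y")))
  # y is an exact multiple of x, so the inner lm fits perfectly
  fit <- suppressWarnings(fit_plspm(dat, model))
  expect_true(fit$converged)
  expect_equal(fit$paths["X", "Y"], 0.8 * sd(x) / sd(0.8 * x),
               tolerance = 1e-8)
  expect_equal(fit$paths["X", "Y"], 1, tolerance = 1e-8)  # deterministic y
})

test_that("single-indicator models equal the OLS path-analysis oracle", {
  set.seed(92)
  n <- 200
  e <- rnorm(n)
  f <- -0.5 * e + rnorm(n, 0, 0.8)
  w <- 0.4 * e + 0.5 * f + rnorm(n, 0, 0.7)
  b <- -0.7 * e - 0.2 * f - 0.1 * w + rnorm(n, 0, 0.6)
  dat <- data.frame(e = e, f = f, w = w, b = b)
  model <- path_model(
    blocks = list(E = "e", F = "f", W = "w", B = "b"),
    edges = rbind(c("E", "F"), c("E", "W"), c("F", "W"),
                  c("E", "B"), c("F", "B"), c("W", "B")))
  fit <- fit_plspm(dat, model)
  oracle <- ols_paths(dat, model)
  for (l in names(oracle)) {
    expect_equal(unname(fit$paths[names(oracle[[l]]), l]),
                 unname(oracle[[l]]), tolerance = 1e-8)
  }
  expect_true(all(fit$r2 > 0))
})

test_that("duplicating every row leaves the estimates unchanged", {
  set.seed(93)
  cfg <- sim_config(seed = 17, n_sites = 60)
  st <- simulate_study(cfg)
  dat <- sem_indicators(st)
  model <- biodiversity_path_model()
  f1 <- fit_plspm(dat, model)
  f2 <- fit_plspm(rbind(dat, dat), model)
  expect_equal(f1$paths, f2$paths, tolerance = 1e-8)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("flipping an indicator's sign leaves |path coefficients| unchanged", {
  cfg <- sim_config(seed = 18, n_sites = 80)
  st <- simulate_study(cfg)
  dat <- sem_indicators(st)
  model <- biodiversity_path_model()
  f1 <- fit_plspm(dat, model)
  dat2 <- dat
  dat2$TN <- -dat2$TN
  f2 <- fit_plspm(dat2, model)
  expect_equal(abs(f1$paths), abs(f2$paths), tolerance = 1e-6)
  # the flipped indicator's weight changes sign
  expect_equal(sign(f2$weights$water_quality[["TN"]]),
               -sign(f1$weights$water_quality[["TN"]]))
})

test_that("all three inner weighting schemes give close estimates here", {
  cfg <- sim_config(seed = 19, n_sites = 200)
  st <- simulate_study(cfg)
  dat <- sem_indicators(st)
  est <- sapply(c("centroid", "factorial", "path"), function(s) {
    fit_plspm(dat, biodiversity_path_model(scheme = s))$path_table$estimate
  })
  expect_lt(max(abs(est[, "centroid"] - est[, "factorial"])), 0.05)
  expect_lt(max(abs(est[, "centroid"] - est[, "path"])), 0.05)
})

test_that("effects decompose into direct plus products over directed paths", {
  model <- path_model(blocks = list(A = "a", B = "b", C = "c"),
                      edges = rbind(c("A", "B"), c("B", "C")))
  fake <- structure(list(
    paths = matrix(c(NA, NA, NA, 0.5, NA, NA, NA, 0.4, NA), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    model = model), class = "plspm_fit")
  eff <- effects_decomposition(fake)
  ac <- eff[eff$from == "A" & eff$to == "C", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
})

test_that("the six-edge topology with unit coefficients sums its three routes", {
  model <- biodiversity_path_model()
  paths <- matrix(NA_real_, 4, 4, dimnames = list(model$latents,
                                                  model$latents))
  paths[model$inner] <- 1
  fake <- structure(list(paths = paths, model = model),
                    class = "plspm_fit")
  eff <- effects_decomposition(fake)
  eb <- eff[eff$from == "elevation" & eff$to == "biodiversity", ]
  # footprint route + WQ route + footprint->WQ route
  expect_equal(eb$indirect, 3)
  expect_equal(eb$total, 4)
  # a chain-free edge has no indirect component
  ef <- eff[eff$from == "elevation" & eff$to == "footprint", ]
  expect_equal(ef$indirect, 0)
})

test_that("total always equals direct plus indirect on fitted models", {
  cfg <- sim_config(seed = 23, n_sites = 120)
  st <- simulate_study(cfg)
  fit <- fit_plspm(sem_indicators(st), biodiversity_path_model())
  eff <- effects_decomposition(fit)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic and minimal under strong signal", {
  cfg <- sim_config(seed = 25, n_sites = 100)
  st <- simulate_study(cfg)
  dat <- sem_indicators(st)
  model <- biodiversity_path_model()
  p1 <- permutation_test(dat, model, n_perm = 49, seed = 7)
  p2 <- permutation_test(dat, model, n_perm = 49, seed = 7)
  expect_equal(p1$p_perm, p2$p_perm)
  # strong structural signal: elevation-rooted paths at the minimum p
  strong <- p1[p1$from == "elevation", ]
  expect_true(all(strong$p_perm <= 3 / 50))
})

test_that("pure-noise indicators yield mostly non-significant paths", {
  set.seed(94)
  flagged <- 0; total <- 0
  for (rep in 1:5) {
    n <- 60
    dat <- data.frame(elevation = rnorm(n), footprint = rnorm(n),
                      TP = rnorm(n), TN = rnorm(n), BOD5 = rnorm(n),
                      TOC = rnorm(n), TD = rnorm(n), FD = rnorm(n),
                      GD = rnorm(n))
    p <- suppressWarnings(permutation_test(dat, biodiversity_path_model(),
                                           n_perm = 99, seed = rep))
    flagged <- flagged + sum(p$p_perm < 0.05)
    total <- total + nrow(p)
  }
  expect_lte(flagged / total, 0.2)
})

test_that("constant indicators and unknown columns are rejected", {
  dat <- data.frame(x = rep(1, 10), y = rnorm(10))
  model <- path_model(blocks = list(X = "x", Y = "y"),
                      edges = rbind(c("X", "Y")))
  expect_error(fit_plspm(dat, model), "constant indicator")
  model2 <- path_model(blocks = list(X = "missing_col", Y = "y"),
                       edges = rbind(c("X", "Y")))
  expect_error(fit_plspm(dat, model2), "lacks indicator")
  expect_error(path_model(blocks = list(A = "a", B = "b"),
                          edges = rbind(c("A", "B"), c("B", "A"))),
               "acyclic")
})
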