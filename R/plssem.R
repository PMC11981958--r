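#' Specify a PLS path model
#'
#' A path model is an ordered set of latent variables, an indicator block
#' per latent, a measurement mode per block (`"A"` reflective, `"B"`
#' formative), and an acyclic inner structure of directed edges between
#' latents (each edge must point from an earlier to a later latent in the
#' given order).
#'
#' @param blocks Named list: latent name -> character vector of indicator
#'   column names. Latent order is the list order.
#' @param edges Two-column matrix or data frame of directed edges
#'   (`from`, `to`) between latent names.
#' @param modes Named character vector of `"A"`/`"B"` per latent; defaults
#'   to `"B"` (formative) for every block.
#' @param scheme Inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @return Object of class `path_model` with elements `latents`, `blocks`,
#'   `modes`, `inner` (logical from x to adjacency matrix), `scheme`.
#' @export
path_model <- function(blocks, edges, modes = NULL,
                       scheme = c("centroid", "factorial", "path")) {
  scheme <- match.arg(scheme)
  latents <- names(blocks)
  if (is.null(latents) || anyDuplicated(latents)) {
    stop("blocks must be a uniquely named list", call. = FALSE)
  }
  ind <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(ind)) {
    stop("every indicator may belong to exactly one block; duplicated: ",
         ind[duplicated(ind)][1], call. = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  if (!all(c(edges$from, edges$to) %in% latents)) {
    stop("edges refer to unknown latents", call. = FALSE)
  }
  inner <- matrix(FALSE, length(latents), length(latents),
                  dimnames = list(latents, latents))
  inner[cbind(edges$from, edges$to)] <- TRUE
  if (any(inner[lower.tri(inner, diag = TRUE)]) || any(inner & t(inner))) {
    stop("inner structure must be acyclic and follow the latent order",
         call. = FALSE)
  }
  if (is.null(modes)) modes <- setNames(rep("B", length(latents)), latents)
  stopifnot(all(modes[latents] %in% c("A", "B")))
  structure(list(latents = latents, blocks = blocks, modes = modes[latents],
                 inner = inner, scheme = scheme),
            class = "path_model")
}

#' The elevation-footprint-water quality-biodiversity path model
#'
#' Elevation and footprint are single-indicator blocks; the four water
#' chemistry indicators (TP, TN, BOD5, TOC) form the water-quality block
#' and the three facets (TD, FD, GD) the biodiversity block, both
#' formative (Mode B). Six directed edges: elevation -> footprint,
#' elevation -> water quality, footprint -> water quality, and all three
#' into biodiversity. Water quality is read as a pressure: higher scores
#' mean worse water.
#'
#' @inheritParams path_model
#' @return A [path_model()].
#' @export
biodiversity_path_model <- function(scheme = "centroid") {
  path_model(
    blocks = list(elevation = "elevation", footprint = "footprint",
                  water_quality = c("TP", "TN", "BOD5", "TOC"),
                  biodiversity = c("TD", "FD", "GD")),
    edges = rbind(c("elevation", "footprint"),
                  c("elevation", "water_quality"),
                  c("footprint", "water_quality"),
                  c("elevation", "biodiversity"),
                  c("footprint", "biodiversity"),
                  c("water_quality", "biodiversity")),
    scheme = scheme)
}

#' Orient a weight vector so the block score correlates positively with
#' its indicators overall (tie: first weight positive)
#' @noRd
orient_block <- function(w, Xb, score) {
  s <- sum(cor(Xb, score))
  if (abs(s) < 1e-12) s <- sign(w[1])
  if (s < 0) -w else w
}

#' Fit a PLS path model (Lohmoeller algorithm)
#'
#' Indicators are standardized; outer weights start at 1 and are iterated:
#' latent scores as standardized weighted sums, inner weights by the
#' chosen scheme (centroid: signs of score correlations along inner
#' edges; factorial: the correlations; path: regression coefficients for
#' predecessors, correlations for successors), and outer updates by Mode A
#' (indicator-score covariances) or Mode B (regression of the inner score
#' on the block's indicators), until the largest absolute outer-weight
#' change drops below `tol` or `max_iter` is reached. Path coefficients
#' are then per-equation least squares of each endogenous latent's scores
#' on its predecessors' scores. Block score signs follow a fixed
#' convention: each latent is oriented so the sum of its indicator
#' correlations is positive.
#'
#' @param data Data frame holding every indicator column (no missing
#'   cells).
#' @param model A [path_model()].
#' @param tol Convergence tolerance on outer weights.
#' @param max_iter Iteration cap; non-convergence is flagged, not an
#'   error.
#' @return Object of class `plspm_fit`: `weights`, `loadings`, `scores`,
#'   `paths` (from x to coefficient matrix), `path_table`, `r2`,
#'   `iterations`, `converged`, `model`.
#' @export
fit_plspm <- function(data, model, tol = 1e-6, max_iter = 300L) {
  stopifnot(inherits(model, "path_model"))
  ind <- unlist(model$blocks, use.names = FALSE)
  miss <- setdiff(ind, names(data))
  if (length(miss)) stop("data lacks indicator(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[, ind, drop = FALSE])
  if (anyNA(X)) stop("indicator data has missing cells", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("constant indicator(s): ",
                          paste(ind[sds == 0], collapse = ", "), call. = FALSE)
  X <- scale(X)
  n <- nrow(X)
  latents <- model$latents
  adj <- model$inner | t(model$inner)   # symmetric adjacency
  W <- lapply(model$blocks, function(b) rep(1, length(b)))
  score_of <- function(W) {
    Y <- vapply(latents, function(l) {
      s <- X[, model$blocks[[l]], drop = FALSE] %*% W[[l]]
      as.numeric(s) / sd(s)
    }, numeric(n))
    colnames(Y) <- latents
    Y
  }
  Y <- score_of(W)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- cor(Y)
    E <- matrix(0, length(latents), length(latents),
                dimnames = list(latents, latents))
    for (l in latents) {
      nb <- latents[adj[, l]]
      if (!length(nb)) next
      if (model$scheme == "centroid") {
        E[nb, l] <- sign(R[nb, l])
      } else if (model$scheme == "factorial") {
        E[nb, l] <- R[nb, l]
      } else {            # path scheme
        preds <- latents[model$inner[, l]]
        succs <- setdiff(nb, preds)
        if (length(preds)) {
          E[preds, l] <- solve(R[preds, preds, drop = FALSE],
                               R[preds, l, drop = FALSE])
        }
        if (length(succs)) E[succs, l] <- R[succs, l]
      }
    }
    Z <- Y %*% E
    W_new <- W
    for (l in latents) {
      Xb <- X[, model$blocks[[l]], drop = FALSE]
      z <- Z[, l]
      if (sd(z) == 0) z <- Y[, l]    # isolated latent: keep its own score
      w <- if (model$modes[[l]] == "A") {
        as.numeric(cov(Xb, z))
      } else {
        as.numeric(solve(cov(Xb), cov(Xb, z)))
      }
      s <- as.numeric(Xb %*% w)
      w <- w / sd(s)
      W_new[[l]] <- orient_block(w, Xb, as.numeric(Xb %*% w))
    }
    delta <- max(abs(unlist(W_new) - unlist(W)))
    W <- W_new
    Y <- score_of(W)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("PLS outer weights did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")", call. = FALSE)
  }
  # inner model: per-equation OLS on standardized scores
  paths <- matrix(NA_real_, length(latents), length(latents),
                  dimnames = list(latents, latents))
  r2 <- setNames(rep(NA_real_, length(latents)), latents)
  for (l in latents) {
    preds <- latents[model$inner[, l]]
    if (!length(preds)) next
    fit <- lm(Y[, l] ~ Y[, preds, drop = FALSE])
    paths[preds, l] <- unname(coef(fit))[-1]
    r2[l] <- summary(fit)$r.squared
  }
  edge_idx <- which(model$inner, arr.ind = TRUE)
  path_table <- data.frame(
    from = latents[edge_idx[, 1]], to = latents[edge_idx[, 2]],
    estimate = paths[edge_idx], stringsAsFactors = FALSE)
  path_table <- path_table[order(match(path_table$to, latents),
                                 match(path_table$from, latents)), ]
  rownames(path_table) <- NULL
  loadings <- lapply(latents, function(l) {
    as.numeric(cor(X[, model$blocks[[l]], drop = FALSE], Y[, l]))
  })
  names(loadings) <- latents
  W <- lapply(latents, function(l) setNames(W[[l]], model$blocks[[l]]))
  names(W) <- latents
  structure(list(weights = W, loadings = loadings, scores = Y, paths = paths,
                 path_table = path_table, r2 = r2[!is.na(r2)],
                 iterations = iter, converged = converged, model = model),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat("PLS path model (", x$model$scheme, "scheme ),",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$path_table, digits = 4)
  cat("R2:", paste(names(x$r2), round(x$r2, 3), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Direct, indirect and total effects
#'
#' For each ordered latent pair, the direct effect is the edge coefficient
#' (0 when absent), the indirect effect the sum over all directed paths of
#' length >= 2 of the products of their edge coefficients, and the total
#' their sum.
#'
#' @param fit A [fit_plspm()] result.
#' @return Data frame: `from`, `to`, `direct`, `indirect`, `total` for
#'   every pair connected by at least one directed path.
#' @export
effects_decomposition <- function(fit) {
  model <- fit$model
  latents <- model$latents
  coefs <- fit$paths
  coefs[is.na(coefs)] <- 0
  # path products via DFS
  indirect <- direct <- matrix(0, length(latents), length(latents),
                               dimnames = dimnames(coefs))
  direct[model$inner] <- coefs[model$inner]
  walk <- function(node, target, prod, len) {
    total <- 0
    for (nxt in latents[model$inner[node, ]]) {
      p <- prod * coefs[node, nxt]
      if (nxt == target && len + 1 >= 2) total <- total + p
      total <- total + walk(nxt, target, p, len + 1)
    }
    total
  }
  for (a in latents) for (b in latents) {
    if (a == b) next
    indirect[a, b] <- walk(a, b, 1, 0)
  }
  keep <- which(direct != 0 | indirect != 0, arr.ind = TRUE)
  out <- data.frame(from = latents[keep[, 1]], to = latents[keep[, 2]],
                    direct = direct[keep], indirect = indirect[keep],
                    stringsAsFactors = FALSE)
  out$total <- out$direct + out$indirect
  out <- out[order(match(out$to, latents), match(out$from, latents)), ]
  rownames(out) <- NULL
  out
}

#' Permutation test of the path coefficients
#'
#' The rows of the exogenous blocks' indicators (latents without incoming
#' edges) are permuted jointly `n_perm` times and the model refitted; the
#' p-value of each path is `(1 + #{|coef_perm| >= |coef_obs|}) /
#' (n_perm + 1)`.
#'
#' @param data Indicator data frame.
#' @param model A [path_model()].
#' @param n_perm Number of permutations (the workflow default is 100).
#' @param seed RNG seed.
#' @param ... Passed to [fit_plspm()].
#' @return The observed `path_table` with an added `p_perm` column;
#'   attribute `fit` carries the observed fit.
#' @export
permutation_test <- function(data, model, n_perm = 100L, seed = 1L, ...) {
  fit <- fit_plspm(data, model, ...)
  obs <- abs(fit$path_table$estimate)
  exo <- model$latents[colSums(model$inner) == 0]
  exo_cols <- unlist(model$blocks[exo], use.names = FALSE)
  count <- numeric(length(obs))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample(nrow(data))
    d2 <- data
    d2[, exo_cols] <- data[perm, exo_cols, drop = FALSE]
    f2 <- suppressWarnings(fit_plspm(d2, model, ...))
    count <- count + (abs(f2$path_table$estimate) >= obs)
  }
  out <- fit$path_table
  out$p_perm <- (1 + count) / (n_perm + 1)
  attr(out, "fit") <- fit
  out
}
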