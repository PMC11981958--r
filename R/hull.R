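#' Volume of the convex hull of a point cloud
#'
#' Exact hull volume in any (small) dimension: segment length in 1-D,
#' shoelace polygon area on the 2-D hull, and an incremental
#' beneath-beyond facet construction in 3-D and above, with the volume
#' accumulated as simplices fanned from an interior point. Degenerate
#' (affinely deficient) clouds have volume 0.
#'
#' @param pts Numeric matrix, points x dimensions.
#' @return Non-negative hull volume (area in 2-D, length in 1-D).
#' @export
chull_volume <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts); d <- ncol(pts)
  if (n == 0) return(0)
  if (affine_rank(pts) < d) return(0)
  if (d == 1) return(max(pts[, 1]) - min(pts[, 1]))
  if (d == 2) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    x <- pts[h, 1]; y <- pts[h, 2]
    return(abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2)
  }
  hull_volume_nd(pts)
}

#' Affine rank of a point set (dimension of its affine hull)
#' @noRd
affine_rank <- function(pts) {
  if (nrow(pts) < 2) return(0)
  centered <- sweep(pts, 2, colMeans(pts))
  qr(centered)$rank
}

#' Hyperplane (outward normal, offset) through d points, oriented away
#' from `inside`
#' @noRd
facet_plane <- function(verts, inside) {
  d <- ncol(verts)
  a <- verts[-1, , drop = FALSE] - matrix(verts[1, ], d - 1, d, byrow = TRUE)
  # normal spans the null space of a
  qr_a <- qr(t(a))
  normal <- qr.Q(qr_a, complete = TRUE)[, d]
  offset <- sum(normal * verts[1, ])
  if (sum(normal * inside) > offset) {
    normal <- -normal; offset <- -offset
  }
  list(normal = normal, offset = offset)
}

#' Incremental convex hull volume for d >= 3
#' @noRd
hull_volume_nd <- function(pts) {
  n <- nrow(pts); d <- ncol(pts)
  scale_eps <- 1e-9 * max(1, max(abs(pts)))
  # initial simplex: greedily pick d+1 affinely independent points
  simplex <- 1L
  for (i in 2:n) {
    cand <- c(simplex, i)
    if (affine_rank(pts[cand, , drop = FALSE]) == length(cand) - 1L) {
      simplex <- cand
    }
    if (length(simplex) == d + 1L) break
  }
  if (length(simplex) < d + 1L) return(0)
  inside <- colMeans(pts[simplex, , drop = FALSE])
  # facets stored as integer vertex sets plus their plane
  facets <- lapply(seq_len(d + 1L), function(k) {
    v <- simplex[-k]
    c(list(verts = v), facet_plane(pts[v, , drop = FALSE], inside))
  })
  rest <- setdiff(seq_len(n), simplex)
  for (p in rest) {
    x <- pts[p, ]
    vis <- vapply(facets, function(f) {
      sum(f$normal * x) > f$offset + scale_eps
    }, logical(1))
    if (!any(vis)) next
    # horizon ridges: (d-1)-subsets appearing in exactly one visible facet
    ridges <- list()
    for (f in facets[vis]) {
      for (k in seq_len(d)) {
        r <- sort(f$verts[-k])
        key <- paste(r, collapse = "-")
        ridges[[key]] <- if (is.null(ridges[[key]])) list(r = r, n = 1L) else
          list(r = r, n = ridges[[key]]$n + 1L)
      }
    }
    horizon <- Filter(function(e) e$n == 1L, ridges)
    facets <- facets[!vis]
    for (e in horizon) {
      v <- c(e$r, p)
      facets[[length(facets) + 1L]] <-
        c(list(verts = v), facet_plane(pts[v, , drop = FALSE], inside))
    }
  }
  vol <- 0
  for (f in facets) {
    m <- pts[f$verts, , drop = FALSE] -
      matrix(inside, d, d, byrow = TRUE)
    vol <- vol + abs(det(m))
  }
  vol / factorial(d)
}
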