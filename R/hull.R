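#' Convex hull volume and vertices in low dimension
#'
#' Computes the volume of the convex hull of a point set and the indices of
#' its vertices (extreme points), for 1--6 dimensions. One dimension is the
#' range, two dimensions use the monotone-chain hull and the shoelace
#' formula, and three or more dimensions use facet enumeration: every
#' supporting hyperplane through d affinely independent points with all
#' remaining points on one side is a facet; the volume is the sum of pyramid
#' volumes facet-area * height / d measured from the centroid, with facet
#' areas obtained by recursion in the facet's hyperplane. Intended for the
#' small point sets (tens of species) arising in trait-space analyses.
#'
#' @param points A numeric matrix, one row per point.
#' @return A list with \code{volume} (0 when the points are affinely
#'   degenerate), \code{vertices} (row indices of the extreme points; for
#'   degenerate inputs the extreme points of the affine span are still
#'   reported when the dimension is 1 or 2 lower), and \code{degenerate}.
#' @export
#' @examples
#' convex_hull(rbind(c(0, 0), c(1, 0), c(0, 1)))$volume  # 0.5
convex_hull <- function(points) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) abort("`points` must be finite.")
  d <- ncol(p)
  if (d > 6) abort("convex_hull() supports at most 6 dimensions.")
  scale <- max(apply(p, 2, function(x) diff(range(x))), 1)
  tol <- 1e-9 * scale
  rk <- affine_rank(p, tol)
  if (nrow(p) <= d || rk < d) {
    return(list(volume = 0, vertices = degenerate_vertices(p, rk, tol),
                degenerate = TRUE))
  }
  res <- hull_rec(p, seq_len(nrow(p)), tol)
  list(volume = res$volume, vertices = sort(res$vertices), degenerate = FALSE)
}

affine_rank <- function(p, tol) {
  if (nrow(p) < 2) return(0)
  q <- sweep(p, 2, colMeans(p))
  sum(svd(q, nu = 0, nv = 0)$d > tol)
}

# vertices of a degenerate set: project onto its affine span and recurse there
degenerate_vertices <- function(p, rk, tol) {
  if (rk == 0) return(1L)
  q <- sweep(p, 2, colMeans(p))
  basis <- svd(q, nv = ncol(p))$v[, seq_len(rk), drop = FALSE]
  proj <- q %*% basis
  sort(hull_rec(proj, seq_len(nrow(p)), tol)$vertices)
}

# recursive worker: p is full-rank in its ncol(p) dims; idx maps rows to the
# caller's original indices
hull_rec <- function(p, idx, tol) {
  d <- ncol(p)
  if (d == 1) {
    v <- c(idx[which.min(p[, 1])], idx[which.max(p[, 1])])
    return(list(volume = diff(range(p[, 1])), vertices = unique(v)))
  }
  if (d == 2) {
    h <- grDevices::chull(p[, 1], p[, 2])
    x <- p[h, 1]; y <- p[h, 2]
    area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    return(list(volume = area, vertices = idx[h]))
  }
  n <- nrow(p)
  centroid <- colMeans(p)
  combos <- utils::combn(n, d)
  normals <- facet_normals(p, combos, d)
  len <- sqrt(rowSums(normals^2))
  ok <- len > tol
  normals <- normals[ok, , drop = FALSE] / len[ok]
  combos <- combos[, ok, drop = FALSE]
  # signed distances of every point from every candidate plane
  s <- normals %*% t(p) -
    rowSums(normals * p[combos[1, ], , drop = FALSE])
  smax <- do.call(pmax, as.data.frame(s))
  smin <- do.call(pmin, as.data.frame(s))
  supporting <- which(smax <= tol | smin >= -tol)

  seen <- new.env(parent = emptyenv())
  volume <- 0
  vertices <- integer(0)
  for (j in supporting) {
    on_plane <- abs(s[j, ]) <= tol
    key <- paste(which(on_plane), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    face_rows <- which(on_plane)
    base <- p[combos[1, j], ]
    normal <- normals[j, ]
    basis <- qr.Q(qr(cbind(normal)), complete = TRUE)[, -1, drop = FALSE]
    proj <- sweep(p[face_rows, , drop = FALSE], 2, base) %*% basis
    sub <- hull_rec(proj, idx[face_rows], tol)
    h <- abs(sum((centroid - base) * normal))
    volume <- volume + sub$volume * h / d
    vertices <- union(vertices, sub$vertices)
  }
  list(volume = volume, vertices = vertices)
}

# normals of the hyperplanes through each d-point combination, computed by
# the generalized cross product of the d - 1 edge vectors (closed form in
# 3 and 4 dimensions, QR null space above that); degenerate combinations
# yield near-zero normals and are filtered by the caller
facet_normals <- function(p, combos, d) {
  base <- p[combos[1, ], , drop = FALSE]
  edges <- lapply(2:d, function(r) p[combos[r, ], , drop = FALSE] - base)
  if (d == 3) {
    u <- edges[[1]]; v <- edges[[2]]
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  } else if (d == 4) {
    u <- edges[[1]]; v <- edges[[2]]; w <- edges[[3]]
    det3 <- function(c1, c2, c3) {
      u[, c1] * (v[, c2] * w[, c3] - v[, c3] * w[, c2]) -
        u[, c2] * (v[, c1] * w[, c3] - v[, c3] * w[, c1]) +
        u[, c3] * (v[, c1] * w[, c2] - v[, c2] * w[, c1])
    }
    cbind(det3(2, 3, 4), -det3(1, 3, 4), det3(1, 2, 4), -det3(1, 2, 3))
  } else {
    t(vapply(seq_len(ncol(combos)), function(j) {
      q <- vapply(edges, function(e) e[j, ], numeric(d))
      dec <- qr(q)
      if (dec$rank < d - 1) return(rep(0, d))
      qr.Q(dec, complete = TRUE)[, d]
    }, numeric(d)))
  }
}
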