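# Planar polygon primitives used by the fibre mosaic and capillary-domain
# tessellation. Polygons are n x 2 matrices of vertices (no repeated closing
# vertex); coordinates are in micrometres throughout.

#' Polygon area by the shoelace formula
#'
#' @param poly An n x 2 matrix of vertices (open ring, any orientation).
#' @return Area in squared coordinate units.
#' @keywords internal
poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
poly_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  nxt <- c(2:n, 1L)
  cr <- x * y[nxt] - x[nxt] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[nxt]) * cr), sum((y + y[nxt]) * cr)) / (6 * a)
}

#' Clip a convex polygon by the half-plane a*x + b*y <= c
#'
#' Sutherland-Hodgman against a single line. Returns a matrix with zero rows
#' when the polygon is entirely outside.
#' @keywords internal
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  f <- a * poly[, 1L] + b * poly[, 2L] - c
  scale <- max(abs(a), abs(b), 1)
  inside <- f <= 1e-9 * scale
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0L, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L
      out[m, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- f[i] / (f[i] - f[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

rect_poly <- function(xlim, ylim) {
  matrix(c(xlim[1L], ylim[1L],
           xlim[2L], ylim[1L],
           xlim[2L], ylim[2L],
           xlim[1L], ylim[2L]), ncol = 2L, byrow = TRUE)
}

#' Voronoi tessellation of points clipped to a rectangle
#'
#' Each cell is obtained by successively clipping the bounding rectangle with
#' the perpendicular bisector against every other generator, visiting
#' generators in order of distance and stopping once the bisector provably
#' cannot intersect the current cell. O(n * k) with k the effective number of
#' neighbours; exact for the Euclidean nearest-point partition.
#'
#' @param x,y Generator coordinates.
#' @param xlim,ylim Rectangle bounds.
#' @param which Indices of generators whose cells are wanted (default all).
#'   Cells are still clipped against every generator.
#' @return List of cell polygons (n x 2 matrices), one per `which`.
#' @keywords internal
voronoi_cells <- function(x, y, xlim, ylim, which = seq_along(x)) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  rect <- rect_poly(xlim, ylim)
  cells <- vector("list", length(which))
  for (ci in seq_along(which)) {
    i <- which[ci]
    d2 <- (x - x[i])^2 + (y - y[i])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- rect
    maxr2 <- max((poly[, 1L] - x[i])^2 + (poly[, 2L] - y[i])^2)
    for (j in ord) {
      if (d2[j] > 4 * maxr2) break
      if (d2[j] == 0) stop("duplicate generator points in Voronoi input")
      a <- x[j] - x[i]
      b <- y[j] - y[i]
      cc <- (a * (x[i] + x[j]) + b * (y[i] + y[j])) / 2
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) < 3L) break
      maxr2 <- max((poly[, 1L] - x[i])^2 + (poly[, 2L] - y[i])^2)
    }
    cells[[ci]] <- poly
  }
  cells
}

#' Nearest-generator pixel assignment (rasterised Voronoi oracle)
#'
#' Brute-force assignment of pixel centres to the nearest generator, used as
#' an independent check of the polygon tessellation. 0-based row-major pixels
#' of size `px`; pixel (r, c) has centre (xlim[1] + (c + 0.5) px,
#' ylim[1] + (r + 0.5) px).
#'
#' @return Vector of per-generator pixel-count areas (pixel count * px^2).
#' @keywords internal
pixel_domain_areas <- function(x, y, xlim, ylim, px = 0.25) {
  nx <- round((xlim[2L] - xlim[1L]) / px)
  ny <- round((ylim[2L] - ylim[1L]) / px)
  gx <- xlim[1L] + (seq_len(nx) - 0.5) * px
  counts <- numeric(length(x))
  # row blocks keep memory flat: nx doubles per generator per block row
  rows_per_block <- max(1L, floor(2e6 / nx))
  r0 <- 0L
  while (r0 < ny) {
    nr <- min(rows_per_block, ny - r0)
    gy <- ylim[1L] + (r0 + seq_len(nr) - 0.5) * px
    X <- rep(gx, times = nr)
    Y <- rep(gy, each = nx)
    best <- rep.int(1L, length(X))
    bestd <- (X - x[1L])^2 + (Y - y[1L])^2
    for (k in seq_along(x)[-1L]) {
      d <- (X - x[k])^2 + (Y - y[k])^2
      upd <- d < bestd
      best[upd] <- k
      bestd[upd] <- d[upd]
    }
    tb <- tabulate(best, nbins = length(x))
    counts <- counts + tb
    r0 <- r0 + nr
  }
  counts * px^2
}
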