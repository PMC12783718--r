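#' Outline utilities
#'
#' An outline is an ordered set of vertices of a simple closed polygon in
#' continuous 2-D coordinates, stored as an n x 2 matrix with columns `x`
#' (column direction) and `y` (row direction), counter-clockwise (positive
#' shoelace area), with the first point not repeated at the end.
#'
#' @param points an n x 2 numeric matrix of vertices.
#' @return an object of class `outline` (an n x 2 matrix).
#' @export
as_outline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3) {
    stop("an outline needs an n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (!all(is.finite(points))) stop("outline has non-finite coordinates", call. = FALSE)
  # drop a duplicated closing vertex
  n <- nrow(points)
  if (isTRUE(all.equal(points[1, ], points[n, ], tolerance = 1e-12,
                       check.attributes = FALSE))) {
    points <- points[-n, , drop = FALSE]
  }
  if (poly_area(points) < 0) points <- points[rev(seq_len(nrow(points))), ]
  dimnames(points) <- list(NULL, c("x", "y"))
  class(points) <- c("outline", "matrix", "array")
  points
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param p an n x 2 vertex matrix (closed implicitly).
#' @return the signed area.
#' @export
poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon perimeter
#'
#' @param p an n x 2 vertex matrix (closed implicitly).
#' @return total edge length of the closed polygon.
#' @export
poly_perimeter <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

#' Polygon centroid (area-weighted)
#'
#' @param p an n x 2 vertex matrix.
#' @return length-2 vector (x, y).
#' @export
poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

# Exact second central moments of the polygon region, as the covariance
# matrix of a uniform density over the region. Green's-theorem closed forms;
# no discretization.
poly_covariance <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  ix <- sum((y^2 + y * y2 + y2^2) * cr) / 12      # integral of y^2 dA
  iy <- sum((x^2 + x * x2 + x2^2) * cr) / 12      # integral of x^2 dA
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  m <- matrix(c(iy / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, ix / a - cy^2), 2, 2)
  list(cov = m, area = a, centroid = c(cx, cy))
}

#' Moment-based best-fitting ellipse of a polygon region
#'
#' Fits the ellipse whose area-normalized second central moments match the
#' polygon's (the convention behind the usual region-properties "best-fitting
#' ellipse"). For an exact ellipse the fit is exact.
#'
#' @param outline an outline (n x 2 matrix).
#' @return list with `center`, semi-axes `a` >= `b`, `angle` of the major
#'   axis in radians within (-pi/2, pi/2], and full axis lengths
#'   `major_length` = 4*sqrt(lambda1), `minor_length` = 4*sqrt(lambda2).
#' @export
ellipse_fit <- function(outline) {
  pc <- poly_covariance(outline)
  if (abs(pc$area) < 1e-12) stop("degenerate outline: zero area", call. = FALSE)
  e <- eigen(pc$cov, symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  list(center = pc$centroid,
       a = 2 * sqrt(l1), b = 2 * sqrt(l2), angle = ang,
       major_length = 4 * sqrt(l1), minor_length = 4 * sqrt(l2))
}

# Rotate points (n x 2) by angle theta about the origin.
rotate_points <- function(p, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(x = ct * p[, 1] - st * p[, 2],
        y = st * p[, 1] + ct * p[, 2])
}

# Simple-polygon check by segment intersection (O(n^2); used on generated
# shapes at modest n and in validation, not in hot paths).
poly_is_simple <- function(p, eps = 1e-12) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE], eps))) {
      return(FALSE)
    }
  }
  TRUE
}

# Division-free proper-intersection predicate: segments (p1, p2) and each
# (q1[i, ], q2[i, ]) cross iff the endpoints of each straddle the other's
# supporting line (strict orientation signs, scale-relative tolerance).
segments_intersect <- function(p1, p2, q1, q2, eps = 1e-12) {
  cross3 <- function(ax, ay, bx, by, cx, cy) {
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  }
  d1 <- cross3(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
  d2 <- cross3(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
  d3 <- cross3(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p1[1], p1[2])
  d4 <- cross3(q1[, 1], q1[, 2], q2[, 1], q2[, 2], p2[1], p2[2])
  lp <- sum((p2 - p1)^2)
  lq <- (q2[, 1] - q1[, 1])^2 + (q2[, 2] - q1[, 2])^2
  tol <- eps * sqrt(lp * lq)
  (pmin(d1, d2) < -tol & pmax(d1, d2) > tol) &
    (pmin(d3, d4) < -tol & pmax(d3, d4) > tol)
}

# Rasterize a polygon onto an nrow x ncol pixel grid by even-odd scanline
# filling at pixel centers: pixel (r, c) has center (x = c, y = r). Returns a
# logical matrix. `ss` supersamples (ss^2 subpixels averaged) and then the
# result is a numeric coverage matrix in [0, 1].
polygon_raster <- function(poly, nrow_px, ncol_px, ss = 1L) {
  if (ss > 1L) {
    sp <- cbind((poly[, 1] - 0.5) * ss + 0.5, (poly[, 2] - 0.5) * ss + 0.5)
    sub <- polygon_raster(sp, nrow_px * ss, ncol_px * ss, ss = 1L)
    m <- matrix(0, nrow_px, ncol_px)
    for (dr in seq_len(ss)) {
      for (dc in seq_len(ss)) {
        m <- m + sub[seq(dr, by = ss, length.out = nrow_px),
                     seq(dc, by = ss, length.out = ncol_px)]
      }
    }
    return(m / ss^2)
  }
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  mask <- matrix(FALSE, nrow_px, ncol_px)
  rows_list <- vector("list", n)
  xs_list <- vector("list", n)
  for (i in seq_len(n)) {
    ylo <- min(y[i], y2[i]); yhi <- max(y[i], y2[i])
    if (ylo == yhi) next
    rs <- seq.int(max(1L, ceiling(ylo)), min(nrow_px, floor(yhi)))
    rs <- rs[rs >= ylo & rs < yhi]          # half-open rule avoids double counts
    if (!length(rs)) next
    t <- (rs - y[i]) / (y2[i] - y[i])
    rows_list[[i]] <- rs
    xs_list[[i]] <- x[i] + t * (x2[i] - x[i])
  }
  rows <- unlist(rows_list); xs <- unlist(xs_list)
  if (!length(rows)) return(mask)
  o <- order(rows, xs)
  rows <- rows[o]; xs <- xs[o]
  idx <- split(seq_along(rows), rows)
  for (key in names(idx)) {
    r <- as.integer(key)
    cr <- xs[idx[[key]]]
    np <- length(cr) %/% 2
    for (j in seq_len(np)) {
      c1 <- ceiling(cr[2 * j - 1] - 1e-9)
      c2 <- floor(cr[2 * j] + 1e-9)
      c1 <- max(1L, c1); c2 <- min(ncol_px, c2)
      if (c1 <= c2) mask[r, c1:c2] <- TRUE
    }
  }
  mask
}
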