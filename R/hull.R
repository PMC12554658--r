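# From-scratch divide-and-conquer quickhull in 2D, silhouette chain
# decomposition, and Douglas-Peucker chain simplification. Geometry is in
# the (x, y) silhouette plane with x = lateral, y = vertical.

as_xy_matrix <- function(points) {
  m <- as.matrix(points)
  if (is.data.frame(points) && all(c("x", "y") %in% colnames(m))) {
    m <- m[, c("x", "y"), drop = FALSE]
  }
  if (ncol(m) != 2 || anyNA(m) || any(!is.finite(m))) {
    abort("`points` must be finite 2D coordinates (2 columns or x/y).")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Signed side-of-line test
#'
#' `F = X_A (Y_B - Y_P) - Y_A (X_B - X_P) + (X_B Y_P - X_P Y_B)`, the signed
#' double area of triangle A-B-P: zero iff `p` lies on line AB, positive on
#' the left of the directed line A to B, negative on the right. This is the
#' primitive that assigns points to half-planes during hull construction.
#'
#' @param a,b Distinct 2D points (length-2 numeric).
#' @param p A 2D point, or an n x 2 matrix of points (vectorized).
#' @return Signed numeric F, one value per row of `p`.
#' @examples
#' side_of_line(c(0, 0), c(1, 0), c(0, 1)) # 1
#' @export
side_of_line <- function(a, b, p) {
  a <- as.double(a); b <- as.double(b)
  if (isTRUE(all.equal(a, b, tolerance = 0))) abort("`a` and `b` must differ.")
  pm <- if (is.null(dim(p))) matrix(as.double(p), ncol = 2) else as_xy_matrix(p)
  a[1] * (b[2] - pm[, 2]) - a[2] * (b[1] - pm[, 1]) +
    (b[1] * pm[, 2] - pm[, 1] * b[2])
}

#' Perpendicular distance from points to a line
#'
#' With `ca = Y_B - Y_A`, `cb = X_A - X_B`, `cc = X_B Y_A - X_A Y_B`, the
#' distance is `|ca x + cb y + cc| / sqrt(ca^2 + cb^2)`; the line
#' `ca x + cb y + cc = 0` is exactly the line through `a` and `b`. Used to
#' pick the farthest point in each quickhull recursion.
#'
#' @inheritParams side_of_line
#' @return Nonnegative distances, one per row of `p`.
#' @export
point_line_distance <- function(a, b, p) {
  a <- as.double(a); b <- as.double(b)
  if (isTRUE(all.equal(a, b, tolerance = 0))) abort("`a` and `b` must differ.")
  pm <- if (is.null(dim(p))) matrix(as.double(p), ncol = 2) else as_xy_matrix(p)
  ca <- b[2] - a[2]
  cb <- a[1] - b[1]
  cc <- b[1] * a[2] - a[1] * b[2]
  abs(ca * pm[, 1] + cb * pm[, 2] + cc) / sqrt(ca^2 + cb^2)
}

# points strictly right of directed line p -> q, recursively expanded;
# returns row indices (into pts) of hull vertices strictly between p and q
find_hull_side <- function(pts, p, q, tol_f) {
  f <- side_of_line(p, q, pts)
  out <- which(f < -tol_f)
  if (length(out) == 0) return(integer())
  d <- point_line_distance(p, q, pts[out, , drop = FALSE])
  c_idx <- out[which.max(d)]
  cpt <- pts[c_idx, ]
  c(find_hull_side(pts, p, cpt, tol_f), c_idx,
    find_hull_side(pts, cpt, q, tol_f))
}

#' Quickhull: 2D convex hull by divide and conquer
#'
#' Builds the minimal convex polygon containing the point set. The leftmost
#' and rightmost points seed the baseline; each recursion keeps only points
#' strictly outside the current edge (beyond a relative tolerance) and
#' splits at the farthest point, so no global angular sort is needed.
#' Collinear boundary points are not reported as vertices.
#'
#' @param points At least 3 non-collinear 2D points: an n x 2 matrix or a
#'   data frame with columns `x` (lateral) and `y` (vertical).
#' @param tol Relative strict-outside tolerance (default 1e-12, scaled by
#'   the squared coordinate magnitude).
#' @return An object of class `hull2d`: list with `vertices`, a tibble of
#'   the hull corners in counter-clockwise order starting from the leftmost
#'   point, each a member of the input set.
#' @examples
#' quickhull(rbind(c(0, 0), c(4, 0), c(0, 3), c(1, 1)))
#' @export
quickhull <- function(points, tol = 1e-12) {
  pts <- unique(as_xy_matrix(points))
  if (nrow(pts) < 3) abort("need at least 3 distinct points.")
  scale <- max(1, max(abs(pts)))
  tol_f <- tol * scale^2
  ord <- order(pts[, 1], -pts[, 2])
  a_idx <- ord[1]                       # leftmost, ties: topmost
  ord2 <- order(-pts[, 1], pts[, 2])
  b_idx <- ord2[1]                      # rightmost, ties: bottom
  a <- pts[a_idx, ]
  b <- pts[b_idx, ]
  lower <- find_hull_side(pts, a, b, tol_f)
  upper <- find_hull_side(pts, b, a, tol_f)
  if (length(lower) == 0 && length(upper) == 0) {
    abort("all points are collinear; no 2D hull exists.")
  }
  idx <- c(a_idx, lower, b_idx, upper)
  structure(
    list(vertices = tibble::tibble(x = pts[idx, 1], y = pts[idx, 2])),
    class = "hull2d", tol = tol_f
  )
}

#' @export
print.hull2d <- function(x, ...) {
  cat("<hull2d> convex polygon with", nrow(x$vertices), "vertices\n")
  print(x$vertices, n = 12)
  invisible(x)
}

#' @method tidy hull2d
#' @export
tidy.hull2d <- function(x, ...) x$vertices

#' Split a convex hull into left and right silhouette chains
#'
#' Cuts the counter-clockwise vertex cycle at the topmost and bottommost
#' vertices. The run of vertices down the low-lateral side is the left
#' chain, the other run the right chain, each ordered top to bottom. Unique
#' extreme vertices belong to both chains; when several vertices tie for an
#' extreme (a flat cap), the tied vertices become the chain terminals and
#' the connecting cap edge belongs to neither chain.
#'
#' @param hull A `hull2d` object from [quickhull()], or its vertex tibble.
#' @param tie_tol Absolute tolerance for extreme-vertex ties, default
#'   1e-9 times the vertical extent.
#' @return A tibble with columns `chain` (`"left"`/`"right"`), `x`, `y`;
#'   each chain ordered top to bottom.
#' @export
split_chains <- function(hull, tie_tol = NULL) {
  v <- if (inherits(hull, "hull2d")) {
    hull$vertices
  } else {
    m <- as_xy_matrix(hull) # assumed counter-clockwise
    tibble::tibble(x = m[, 1], y = m[, 2])
  }
  n <- nrow(v)
  if (n < 3) abort("degenerate polygon: fewer than 3 vertices.")
  ymax <- max(v$y); ymin <- min(v$y)
  if (is.null(tie_tol)) tie_tol <- 1e-9 * max(ymax - ymin, 1)
  top <- which(v$y > ymax - tie_tol)
  bot <- which(v$y < ymin + tie_tol)
  top_left <- top[which.min(v$x[top])]
  top_right <- top[which.max(v$x[top])]
  bot_left <- bot[which.min(v$x[bot])]
  bot_right <- bot[which.max(v$x[bot])]
  walk <- function(from, to, step) {
    idx <- from
    i <- from
    while (i != to) {
      i <- ((i - 1 + step) %% n) + 1
      idx <- c(idx, i)
    }
    idx
  }
  left_idx <- walk(top_left, bot_left, +1L)   # CCW descends the left side
  right_idx <- walk(top_right, bot_right, -1L)
  dplyr::bind_rows(
    dplyr::mutate(v[left_idx, ], chain = "left", .before = 1),
    dplyr::mutate(v[right_idx, ], chain = "right", .before = 1)
  )
}

# recursive Douglas-Peucker survivor indices on an ordered polyline
dp_keep <- function(m, tol) {
  n <- nrow(m)
  if (n <= 2) return(seq_len(n))
  a <- m[1, ]
  b <- m[n, ]
  mid <- m[2:(n - 1), , drop = FALSE]
  d <- if (isTRUE(all.equal(a, b, tolerance = 0))) {
    sqrt((mid[, 1] - a[1])^2 + (mid[, 2] - a[2])^2)
  } else {
    point_line_distance(a, b, mid)
  }
  imax <- which.max(d)
  if (d[imax] <= tol) return(c(1L, n))
  split <- imax + 1L
  c(dp_keep(m[1:split, , drop = FALSE], tol),
    split - 1L + dp_keep(m[split:n, , drop = FALSE], tol)[-1])
}

#' Simplify a silhouette chain (Douglas-Peucker)
#'
#' Removes chain vertices that deviate from the simplified polyline by at
#' most `tol` perpendicular distance; endpoints are always kept and
#' `tol = 0` is the identity. Dense reconstructed clouds produce silhouette
#' chains with many sampling micro-corners; at the default normalization
#' (height 5) a tolerance of 0.05 (1% of plant height) suppresses them
#' while retaining the architectural corners.
#'
#' @param chain An ordered (top-to-bottom) chain: tibble/matrix with
#'   columns `x`, `y`.
#' @param tol Nonnegative tolerance, default 0.05.
#' @return The simplified chain as a tibble with columns from the input
#'   (`chain` column preserved if present).
#' @export
simplify_chain <- function(chain, tol = 0.05) {
  if (tol < 0) abort("`tol` must be >= 0.")
  m <- as_xy_matrix(if (is.data.frame(chain)) chain[, c("x", "y")] else chain)
  if (nrow(m) <= 2 || tol == 0) {
    return(if (is.data.frame(chain)) tibble::as_tibble(chain) else
      tibble::tibble(x = m[, 1], y = m[, 2]))
  }
  keep <- dp_keep(m, tol)
  if (is.data.frame(chain)) {
    tibble::as_tibble(chain)[keep, ]
  } else {
    tibble::tibble(x = m[keep, 1], y = m[keep, 2])
  }
}
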