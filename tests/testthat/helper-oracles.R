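# Independent brute-force oracles used to cross-check the package's
# geometry and filtering implementations. These deliberately use different
# formulations than the implementation code.

# hull vertex set by the all-pairs half-plane test: (i, j) is a hull edge
# iff every other point lies strictly on its left; a vertex is an endpoint
# of some edge. O(n^3), exact for points in general position.
oracle_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  is_vertex <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pts[j, 1] - pts[i, 1]
      dy <- pts[j, 2] - pts[i, 2]
      cr <- dx * (pts[, 2] - pts[i, 2]) - dy * (pts[, 1] - pts[i, 1])
      if (all(cr[-c(i, j)] > 0)) {
        is_vertex[i] <- TRUE
        is_vertex[j] <- TRUE
      }
    }
  }
  pts[is_vertex, , drop = FALSE]
}

sort_rows <- function(m) {
  m <- unname(as.matrix(m))
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# perpendicular point-line distance via vector projection (independent of
# the line-coefficient formula in the package)
oracle_point_line_dist <- function(a, b, p) {
  ab <- b - a
  ap <- p - a
  t <- sum(ap * ab) / sum(ab * ab)
  sqrt(sum((ap - t * ab)^2))
}

# statistical outlier filter by full distance matrix
oracle_stat_filter_keep <- function(coords, k, std_mult) {
  d <- as.matrix(dist(coords))
  s <- sapply(seq_len(nrow(coords)), function(i) {
    mean(sort(d[i, -i])[seq_len(k)])
  })
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  s >= mu - sigma * std_mult & s <= mu + sigma * std_mult
}

# voxel down-sampling by hash buckets
oracle_voxel <- function(cloud, leaf) {
  p <- as.matrix(cloud[, c("x", "y", "z")])
  mins <- apply(p, 2, min)
  key <- paste(floor((p[, 1] - mins[1]) / leaf),
               floor((p[, 2] - mins[2]) / leaf),
               floor((p[, 3] - mins[3]) / leaf))
  out <- lapply(split(seq_len(nrow(p)), key), function(idx) {
    c(colMeans(p[idx, , drop = FALSE]),
      round(mean(cloud$r[idx])), round(mean(cloud$g[idx])),
      round(mean(cloud$b[idx])))
  })
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Douglas-Peucker survivors by an independent recursive max-deviation scan
oracle_dp <- function(m, tol) {
  rec <- function(lo, hi) {
    if (hi - lo < 2) return(c(lo, hi))
    dev <- sapply((lo + 1):(hi - 1), function(i) {
      oracle_point_line_dist(m[lo, ], m[hi, ], m[i, ])
    })
    i_worst <- (lo:hi)[which.max(dev) + 1]
    if (max(dev) <= tol) return(c(lo, hi))
    union(rec(lo, i_worst), rec(i_worst, hi))
  }
  sort(unique(rec(1, nrow(m))))
}

# Welch's t statistic, Welch-Satterthwaite df and two-sided p, direct
# formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Fleiss' kappa by the textbook formula, written against category counts
oracle_fleiss <- function(m) {
  cats <- sort(unique(as.vector(m)))
  N <- nrow(m)
  n <- ncol(m)
  nij <- matrix(0, N, length(cats))
  for (i in seq_len(N)) {
    for (j in seq_len(n)) nij[i, match(m[i, j], cats)] <-
        nij[i, match(m[i, j], cats)] + 1
  }
  P_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  p_j <- colSums(nij) / (N * n)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# random rigid rotation via QR with positive determinant
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# uniform random colored cloud
random_cloud <- function(n, span = 10) {
  as_point_cloud(tibble::tibble(
    x = runif(n, -span, span), y = runif(n, -span, span),
    z = runif(n, -span, span),
    r = sample(0:255, n, replace = TRUE),
    g = sample(0:255, n, replace = TRUE),
    b = sample(0:255, n, replace = TRUE)
  ))
}

example_hull_chains <- function() {
  path <- system.file("extdata", "example_hull_corners.csv",
                      package = "planthull")
  read.csv(path)
}

validation_labels <- function() {
  path <- system.file("extdata", "validation_labels.csv", package = "planthull")
  read.csv(path)
}
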