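# Preprocessing: coordinate correction, statistical and color denoising,
# voxel down-sampling, and height/width trait extraction. The vertical
# (growth) axis is y throughout.

#' Rigid transform (rotation + translation)
#'
#' @param rotation A 3x3 orthonormal matrix with determinant +1
#'   (tolerance 1e-8).
#' @param translation Length-3 numeric translation, model units.
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform(diag(3), c(0, 1, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.double(translation)
  if (!all(dim(rotation) == c(3, 3)) || anyNA(rotation)) {
    abort("`rotation` must be a numeric 3x3 matrix.")
  }
  if (length(translation) != 3 || anyNA(translation)) {
    abort("`translation` must be a length-3 numeric vector.")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    abort("`rotation` must be orthonormal with determinant +1.")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' Each output coordinate is `rotation %*% p + translation`; colors and the
#' number of points are unchanged. All pairwise distances are preserved.
#'
#' @param cloud A point-cloud tibble.
#' @param transform A [rigid_transform()].
#' @return The transformed point-cloud tibble.
#' @export
apply_rigid_transform <- function(cloud, transform) {
  cloud <- check_cloud(cloud)
  if (!inherits(transform, "rigid_transform")) {
    transform <- rigid_transform(transform$rotation, transform$translation)
  }
  p <- t(as.matrix(cloud[, c("x", "y", "z")]))
  q <- transform$rotation %*% p + transform$translation
  cloud$x <- q[1, ]
  cloud$y <- q[2, ]
  cloud$z <- q[3, ]
  cloud
}

#' Coordinate correction: align the plant's principal axis with vertical
#'
#' Estimates the rigid transform that maps the first principal component of
#' the coordinates (the growth direction of an elongated plant) to the +y
#' axis, with the sign chosen so that the point-count-denser half of the
#' cloud lies above the centroid, and moves the centroid's horizontal
#' position to the origin. Reconstructed clouds routinely come out tilted
#' relative to the true growth direction; applying the returned transform
#' makes the largest-variance direction vertical.
#'
#' @param cloud A point-cloud tibble with at least 3 non-collinear points.
#' @return A [rigid_transform()].
#' @export
principal_axis_transform <- function(cloud) {
  cloud <- check_cloud(cloud, min_points = 3L)
  p <- as.matrix(cloud[, c("x", "y", "z")])
  ctr <- colMeans(p)
  cv <- stats::cov(p)
  eg <- eigen(cv, symmetric = TRUE)
  scale2 <- max(eg$values[1], .Machine$double.eps)
  if (eg$values[2] / scale2 < 1e-12) {
    abort("degenerate point cloud: covariance rank < 2 (points collinear).")
  }
  v1 <- eg$vectors[, 1]
  above <- sum((p %*% v1) > sum(ctr * v1))
  if (above < nrow(p) / 2) v1 <- -v1
  # complete an orthonormal frame; rows (u2, v1, u3) send v1 to +y
  u2 <- eg$vectors[, 2]
  u2 <- u2 - sum(u2 * v1) * v1
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(v1[2] * u2[3] - v1[3] * u2[2],
          v1[3] * u2[1] - v1[1] * u2[3],
          v1[1] * u2[2] - v1[2] * u2[1])
  rot <- rbind(u2, v1, u3)
  dimnames(rot) <- NULL
  if (det(rot) < 0) rot[3, ] <- -rot[3, ]
  rc <- as.double(rot %*% ctr)
  rigid_transform(rot, c(-rc[1], 0, -rc[3]))
}

#' Orient a plant cloud upright
#'
#' Convenience wrapper: applies `transform` if supplied, otherwise the
#' transform estimated by [principal_axis_transform()].
#'
#' @inheritParams apply_rigid_transform
#' @param transform Optional user-supplied [rigid_transform()].
#' @return The oriented point-cloud tibble.
#' @export
orient_plant <- function(cloud, transform = NULL) {
  if (is.null(transform)) transform <- principal_axis_transform(cloud)
  apply_rigid_transform(cloud, transform)
}

# mean distance of each point to its k nearest neighbors, brute force in
# column chunks so memory stays bounded
knn_mean_distance <- function(p, k, chunk = 512L) {
  n <- nrow(p)
  sq <- rowSums(p^2)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * (p[idx, , drop = FALSE] %*% t(p))
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1, function(row) {
      # partial sort partitions the k+1 smallest to the front (unsorted);
      # drop the smallest of them, the self-distance
      nn <- sort.int(sort.int(row, partial = k + 1L)[seq_len(k + 1L)])
      mean(sqrt(nn[-1L]))
    })
  }
  out
}

#' Statistical outlier removal
#'
#' For each point, computes the mean Euclidean distance to its `k` nearest
#' neighbors. Treating these mean distances as a Gaussian sample with mean
#' `mu` and (population) standard deviation `sigma`, points whose mean
#' distance falls outside `[mu - sigma * std_mult, mu + sigma * std_mult]`
#' are discarded as outliers. Input order is preserved.
#'
#' @param cloud A point-cloud tibble with more than `k` points.
#' @param k Neighbor count (default 30).
#' @param std_mult Standard-deviation multiple defining the keep band
#'   (default 1).
#' @return The filtered point-cloud tibble (a subset of the input rows).
#' @export
filter_statistical_outliers <- function(cloud, k = 30, std_mult = 1) {
  cloud <- check_cloud(cloud)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.")
  if (std_mult <= 0) abort("`std_mult` must be > 0.")
  if (nrow(cloud) <= k) {
    abort(paste0("need more than k = ", k, " points (have ", nrow(cloud), ")."))
  }
  s <- knn_mean_distance(as.matrix(cloud[, c("x", "y", "z")]), k)
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  # tiny relative slack so the zero-variance band still contains mu in
  # floating point (perfectly regular clouds keep every point)
  eps <- 1e-9 * (abs(mu) + 1)
  keep <- s >= mu - sigma * std_mult - eps & s <= mu + sigma * std_mult + eps
  cloud[keep, ]
}

#' Color conditional filter
#'
#' Retains exactly the points whose color satisfies
#' `min_rgb <= (r, g, b) <= max_rgb` on every channel. The default keep band
#' drops the near-black noise that SFM-MVS reconstruction leaves along leaf
#' and stem edges (every channel below 41) while keeping plant-colored
#' points. A remove-band is expressible via complementary thresholds.
#'
#' @param cloud A point-cloud tibble.
#' @param min_rgb,max_rgb Integer RGB triples, `0 <= min_rgb <= max_rgb <=
#'   255` channelwise.
#' @return The filtered point-cloud tibble (possibly empty).
#' @export
filter_color <- function(cloud, min_rgb = c(41, 41, 41),
                         max_rgb = c(255, 255, 255)) {
  cloud <- check_cloud(cloud)
  min_rgb <- as.numeric(min_rgb)
  max_rgb <- as.numeric(max_rgb)
  if (length(min_rgb) != 3 || length(max_rgb) != 3 ||
      any(min_rgb < 0) || any(max_rgb > 255) || any(min_rgb > max_rgb)) {
    abort("need 0 <= min_rgb <= max_rgb <= 255 channelwise.")
  }
  keep <- cloud$r >= min_rgb[1] & cloud$r <= max_rgb[1] &
    cloud$g >= min_rgb[2] & cloud$g <= max_rgb[2] &
    cloud$b >= min_rgb[3] & cloud$b <= max_rgb[3]
  cloud[keep, ]
}

#' Voxel-grid down-sampling
#'
#' Partitions space into axis-aligned cubes of edge `leaf` anchored at the
#' cloud's minimum corner and replaces the points of each non-empty voxel by
#' their center of gravity (mean coordinates, channelwise rounded mean
#' color). Geometric features of the cloud are preserved while the point
#' count drops, which is what makes the downstream multi-view hull analysis
#' fast.
#'
#' @param cloud A non-empty point-cloud tibble.
#' @param leaf Voxel edge length (> 0). Default: 2% of the bounding-box
#'   diagonal.
#' @return The down-sampled point-cloud tibble, one point per occupied
#'   voxel, ordered by voxel index (z-major, then y, then x).
#' @export
downsample_voxel <- function(cloud, leaf = NULL) {
  cloud <- check_cloud(cloud, min_points = 1L)
  p <- as.matrix(cloud[, c("x", "y", "z")])
  if (is.null(leaf)) {
    leaf <- 0.02 * sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
    if (leaf <= 0) leaf <- 1 # all points coincide
  }
  if (!is.numeric(leaf) || leaf <= 0) abort("`leaf` must be > 0.")
  mins <- apply(p, 2, min)
  ix <- floor((p[, 1] - mins[1]) / leaf)
  iy <- floor((p[, 2] - mins[2]) / leaf)
  iz <- floor((p[, 3] - mins[3]) / leaf)
  out <- tibble::tibble(ix = ix, iy = iy, iz = iz,
                        x = cloud$x, y = cloud$y, z = cloud$z,
                        r = cloud$r, g = cloud$g, b = cloud$b) |>
    dplyr::group_by(.data$iz, .data$iy, .data$ix) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      r = as.integer(round(mean(.data$r))),
      g = as.integer(round(mean(.data$g))),
      b = as.integer(round(mean(.data$b))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$iz, .data$iy, .data$ix) |>
    dplyr::select(-"ix", -"iy", -"iz")
  as_point_cloud(out, name = attr(cloud, "name", exact = TRUE))
}

#' Extract plant height and width
#'
#' Height is the vertical (y) extent of the cloud; width is the maximum
#' pairwise distance between points projected to the horizontal (x, z)
#' plane — the canopy span a ruler measurement would target.
#'
#' @param cloud A point-cloud tibble with at least 2 points.
#' @return A one-row tibble with columns `height` and `width` (model units).
#' @examples
#' measure_plant(as_point_cloud(expand.grid(x = 0:1, y = 0:1, z = 0:1)))
#' @export
measure_plant <- function(cloud) {
  cloud <- check_cloud(cloud, min_points = 2L)
  height <- max(cloud$y) - min(cloud$y)
  h <- unique(cbind(cloud$x, cloud$z))
  width <- if (nrow(h) < 2) {
    0
  } else if (nrow(h) <= 3) {
    max(stats::dist(h))
  } else {
    v <- h[grDevices::chull(h), , drop = FALSE]
    max(stats::dist(v))
  }
  tibble::tibble(height = height, width = as.double(width))
}
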