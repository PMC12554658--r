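# Rotational multi-view silhouette projection. The plant is rotated about
# the vertical (y) axis in fixed angular steps and orthographically
# projected; each view keeps (u, v) = (vertical, lateral) coordinates.

#' Rotate 3D coordinates about the vertical (y) axis
#'
#' `x' = x cos(theta) + z sin(theta)`, `y' = y`,
#' `z' = -x sin(theta) + z cos(theta)`.
#'
#' @param coords A length-3 numeric vector or an n x 3 matrix / data frame
#'   of `(x, y, z)` coordinates.
#' @param angle_deg Rotation angle in degrees.
#' @return Coordinates of the same shape as the input.
#' @examples
#' rotate_about_vertical(c(1, 2, 0), 90) # (0, 2, -1)
#' @export
rotate_about_vertical <- function(coords, angle_deg) {
  vec_in <- is.null(dim(coords))
  m <- if (vec_in) matrix(as.double(coords), ncol = 3) else
    as.matrix(coords)[, 1:3, drop = FALSE]
  if (anyNA(m) || any(!is.finite(m))) abort("coordinates must be finite.")
  th <- angle_deg * pi / 180
  out <- cbind(m[, 1] * cos(th) + m[, 3] * sin(th),
               m[, 2],
               -m[, 1] * sin(th) + m[, 3] * cos(th))
  if (vec_in) as.double(out) else out
}

#' Project a plant cloud into rotational silhouette views
#'
#' Rotates the cloud about the vertical axis by every multiple of
#' `step_deg` in `[0, 360)` and records, for each view, the 2D silhouette
#' coordinates `(u, v)` = (vertical, lateral) of every point. The default
#' 10-degree step yields 36 views; a 5-degree step yields 72.
#'
#' @param cloud A point-cloud tibble.
#' @param step_deg Angular step in degrees; must divide 360 and satisfy
#'   `0 < step_deg <= 180`.
#' @return A tibble with columns `angle_deg`, `u` (vertical), `v`
#'   (lateral); `360 / step_deg` views of `nrow(cloud)` points each.
#' @export
project_views <- function(cloud, step_deg = 10) {
  cloud <- check_cloud(cloud)
  if (!is.numeric(step_deg) || step_deg <= 0 || step_deg > 180) {
    abort("`step_deg` must be in (0, 180].")
  }
  n_views <- 360 / step_deg
  if (abs(n_views - round(n_views)) > 1e-9) {
    abort("`step_deg` must divide 360 exactly.")
  }
  n_views <- as.integer(round(n_views))
  angles <- (seq_len(n_views) - 1) * step_deg
  purrr::map_dfr(angles, function(a) {
    th <- a * pi / 180
    tibble::tibble(
      angle_deg = a,
      u = cloud$y,
      v = cloud$x * cos(th) + cloud$z * sin(th)
    )
  })
}

#' Normalize a silhouette view to a common height
#'
#' Uniformly scales both axes so that the vertical extent equals
#' `target_height` and shifts the vertical minimum to 0. The corner change
#' rate has units 1/length, so silhouettes must share a common scale for
#' classification intervals to be transferable between plants; this is that
#' scale-fixing step. Idempotent.
#'
#' @param view A tibble with columns `u` and `v` (other columns are kept).
#' @param target_height Target vertical extent (> 0), default 5 model units.
#' @return The rescaled view tibble.
#' @export
normalize_view <- function(view, target_height = 5) {
  if (!all(c("u", "v") %in% names(view))) {
    abort("`view` must have columns `u` and `v`.")
  }
  if (target_height <= 0) abort("`target_height` must be > 0.")
  extent <- max(view$u) - min(view$u)
  if (extent <= 0) abort("view has zero vertical extent.")
  s <- target_height / extent
  view$v <- view$v * s
  view$u <- (view$u - min(view$u)) * s
  view
}
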