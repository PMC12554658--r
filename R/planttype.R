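# Corner change rate K' along silhouette chains, per-plant rate profiles
# over all views, and interval-based plant-type classification.
#
# Eq. convention: for a corner triple, X is the vertical (height)
# coordinate and Y the lateral one;
#   K' = [ (Y3-Y2)/(X3-X2) - (Y2-Y1)/(X2-X1) ] / (X3-X1)
# a second-difference discrete curvature with units 1/length.

#' Corner change rate of a silhouette corner triple
#'
#' @param p1,p2,p3 Corner coordinates as length-2 numerics `(X, Y)` with
#'   `X` the vertical (height) coordinate and `Y` the lateral one.
#' @param tol Vertical gaps below `tol` (default 1e-9) make the triple
#'   degenerate; `NA` is returned so callers can skip it.
#' @return Signed K' (1/length), or `NA` for a degenerate triple.
#' @examples
#' corner_change_rate(c(0, 0), c(1, 1), c(2, 4)) # 1
#' @export
corner_change_rate <- function(p1, p2, p3, tol = 1e-9) {
  p1 <- as.double(p1); p2 <- as.double(p2); p3 <- as.double(p3)
  if (abs(p2[1] - p1[1]) <= tol || abs(p3[1] - p2[1]) <= tol ||
      abs(p3[1] - p1[1]) <= tol) {
    return(NA_real_)
  }
  ((p3[2] - p2[2]) / (p3[1] - p2[1]) - (p2[2] - p1[2]) / (p2[1] - p1[1])) /
    (p3[1] - p1[1])
}

#' Corner change rates along a silhouette chain
#'
#' Slides a window over consecutive corner triples of a top-to-bottom
#' chain and records one sample per triple: the absolute corner change
#' rate `|K'|` and the height of the middle corner. Degenerate triples
#' (tied heights, e.g. flat cap remnants) are skipped; chains with fewer
#' than 3 corners yield no samples.
#'
#' @param chain Chain corners, ordered top to bottom: a tibble/matrix with
#'   columns `x` (lateral) and `y` (vertical).
#' @param view_angle_deg View angle annotation for the samples.
#' @return A tibble with columns `view_angle_deg`, `height`, `rate`.
#' @export
chain_rates <- function(chain, view_angle_deg = NA_real_) {
  m <- as_xy_matrix(if (is.data.frame(chain)) chain[, c("x", "y")] else chain)
  n <- nrow(m)
  empty <- tibble::tibble(view_angle_deg = double(), height = double(),
                          rate = double())
  if (n < 3) return(empty)
  rows <- purrr::map_dfr(seq_len(n - 2), function(i) {
    kp <- corner_change_rate(c(m[i, 2], m[i, 1]),
                             c(m[i + 1, 2], m[i + 1, 1]),
                             c(m[i + 2, 2], m[i + 2, 1]))
    tibble::tibble(view_angle_deg = view_angle_deg,
                   height = m[i + 1, 2], rate = abs(kp))
  })
  rows[!is.na(rows$rate), ]
}

#' Per-plant corner-change-rate profile over all views
#'
#' For every projected view: (optionally) normalize to a common height,
#' build the quickhull, split it into left/right silhouette chains,
#' simplify each chain, and collect the corner change rates of both
#' chains. The pooled samples over all views are the plant's rate profile,
#' the statistic the plant-type intervals are read against.
#'
#' @param views A tibble of projected views from [project_views()]
#'   (columns `angle_deg`, `u`, `v`).
#' @param simplify_tol Chain simplification tolerance (default 0.05 in
#'   normalized units; 0 disables).
#' @param normalize Normalize each view to `target_height` before hull
#'   construction (default TRUE).
#' @param target_height Common vertical extent used by the normalization.
#' @return A tibble of samples: `view_angle_deg`, `height`, `rate`. Views
#'   whose points are collinear are skipped with a warning; an error is
#'   raised if every view is degenerate.
#' @export
plant_rate_profile <- function(views, simplify_tol = 0.05, normalize = TRUE,
                               target_height = 5) {
  if (!all(c("angle_deg", "u", "v") %in% names(views))) {
    abort("`views` must have columns angle_deg, u, v (see project_views()).")
  }
  if (nrow(views) == 0) abort("`views` is empty.")
  skipped <- 0L
  out <- purrr::map_dfr(split(views, views$angle_deg), function(vw) {
    vw2 <- if (normalize) normalize_view(vw, target_height) else vw
    hull <- tryCatch(quickhull(cbind(x = vw2$v, y = vw2$u)),
                     error = function(e) NULL)
    if (is.null(hull)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    chains <- split_chains(hull)
    purrr::map_dfr(split(chains, chains$chain), function(ch) {
      chain_rates(simplify_chain(ch[, c("x", "y")], simplify_tol),
                  view_angle_deg = vw$angle_deg[1])
    })
  })
  if (skipped > 0) {
    warn(paste0(skipped, " view(s) skipped: points collinear."))
  }
  if (skipped == length(unique(views$angle_deg))) {
    abort("all views degenerate: no silhouette hull could be built.")
  }
  dplyr::arrange(out, .data$view_angle_deg, dplyr::desc(.data$height))
}

#' Plant-type classification intervals
#'
#' Closed `|K'|` intervals for the two canopy architecture classes. The
#' defaults are the published ranges: cylinder `[0, 0.2]` (upper and lower
#' canopy of similar width, low silhouette curvature) and tower
#' `[0.4, 1.5]` (wide bottom tapering upward, high curvature).
#'
#' @param cylinder,tower Length-2 numeric `c(low, high)` intervals.
#' @return An object of class `type_intervals`.
#' @export
type_intervals <- function(cylinder = c(0, 0.2), tower = c(0.4, 1.5)) {
  for (iv in list(cylinder, tower)) {
    if (length(iv) != 2 || anyNA(iv) || iv[1] > iv[2]) {
      abort("each interval must be c(low, high) with low <= high.")
    }
  }
  structure(list(cylinder = as.double(cylinder), tower = as.double(tower)),
            class = "type_intervals")
}

#' @export
print.type_intervals <- function(x, ...) {
  cat(sprintf("<type_intervals> cylinder [%g, %g], tower [%g, %g]\n",
              x$cylinder[1], x$cylinder[2], x$tower[1], x$tower[2]))
  invisible(x)
}

#' Classify a plant from its corner-change-rate samples
#'
#' Counts the samples falling into the (closed) cylinder and tower
#' intervals; samples in neither interval count toward neither. The plant
#' is labeled cylinder when the cylinder count strictly exceeds the tower
#' count, otherwise tower (ties included).
#'
#' @param samples A rate-profile tibble from [plant_rate_profile()], or a
#'   numeric vector of `|K'|` values.
#' @param intervals A [type_intervals()] object.
#' @return An object of class `plant_type`: list with `samples`,
#'   `n_cylinder`, `n_tower`, `label`, `intervals`.
#' @examples
#' classify_plant(c(0.05, 0.10, 0.50))$label # "cylinder"
#' @export
classify_plant <- function(samples, intervals = type_intervals()) {
  if (is.numeric(samples)) {
    samples <- tibble::tibble(view_angle_deg = NA_real_, height = NA_real_,
                              rate = as.double(samples))
  }
  if (!"rate" %in% names(samples) || nrow(samples) == 0) {
    abort("`samples` must be a nonempty rate profile (column `rate`).")
  }
  if (!inherits(intervals, "type_intervals")) {
    abort("`intervals` must be a type_intervals() object.")
  }
  r <- samples$rate
  n_cyl <- sum(r >= intervals$cylinder[1] & r <= intervals$cylinder[2])
  n_tow <- sum(r >= intervals$tower[1] & r <= intervals$tower[2])
  structure(
    list(samples = tibble::as_tibble(samples),
         n_cylinder = n_cyl, n_tower = n_tow,
         label = if (n_cyl > n_tow) "cylinder" else "tower",
         intervals = intervals),
    class = "plant_type"
  )
}

#' @export
print.plant_type <- function(x, ...) {
  cat(sprintf(
    "<plant_type> %s (%d samples: %d in cylinder range, %d in tower range)\n",
    x$label, nrow(x$samples), x$n_cylinder, x$n_tower))
  invisible(x)
}

#' @describeIn classify_plant Per-sample tibble of the classified profile.
#' @param x A `plant_type` object.
#' @param ... Unused.
#' @method tidy plant_type
#' @export
tidy.plant_type <- function(x, ...) x$samples

#' @describeIn classify_plant One-row classification summary.
#' @method glance plant_type
#' @export
glance.plant_type <- function(x, ...) {
  tibble::tibble(label = x$label, n_samples = nrow(x$samples),
                 n_cylinder = x$n_cylinder, n_tower = x$n_tower,
                 rate_mean = mean(x$samples$rate),
                 rate_max = max(x$samples$rate))
}

#' Fit classification intervals from labeled rate samples
#'
#' Aggregates pooled `|K'|` samples per plant-type label into per-class
#' intervals: `minmax` takes the observed range; `percentile95` the
#' central 95% range (2.5th to 97.5th percentile, linear interpolation),
#' which resists stray extreme corners.
#'
#' @param rates A tibble with columns `label` (`"cylinder"`/`"tower"`) and
#'   `rate`; at least 2 rates per label.
#' @param method `"minmax"` or `"percentile95"`.
#' @return A [type_intervals()] object.
#' @export
fit_intervals <- function(rates, method = c("minmax", "percentile95")) {
  method <- match.arg(method)
  if (!all(c("label", "rate") %in% names(rates))) {
    abort("`rates` must have columns `label` and `rate`.")
  }
  one <- function(lbl) {
    x <- rates$rate[rates$label == lbl]
    if (length(x) < 2) {
      abort(paste0("need at least 2 rates for label '", lbl, "'."))
    }
    if (method == "minmax") range(x) else
      unname(quantile(x, c(0.025, 0.975), type = 7))
  }
  type_intervals(cylinder = one("cylinder"), tower = one("tower"))
}

#' Student-t 95% confidence interval for a mean
#'
#' `mean +/- t(0.975, n-1) * s / sqrt(n)`, the interval used to summarize
#' the per-class corner-change-rate distributions.
#'
#' @param x Numeric sample, `n >= 2`.
#' @return One-row tibble with `mean`, `low`, `high`.
#' @export
mean_ci95 <- function(x) {
  x <- as.double(x)
  n <- length(x)
  if (n < 2 || anyNA(x)) abort("`x` must have n >= 2 non-missing values.")
  m <- mean(x)
  hw <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  tibble::tibble(mean = m, low = m - hw, high = m + hw)
}
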