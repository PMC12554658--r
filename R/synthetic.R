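# Synthetic surface-of-revolution plant clouds with known plant-type
# ground truth: piecewise-linear radius profiles swept about the vertical
# axis, plant-colored points, optional inward-only radial noise, black
# edge noise and scattered outliers.

#' Plant silhouette profile presets
#'
#' A profile is an ordered list of `(height u, half-width r)` corners, top
#' to bottom, defining a convex piecewise-linear radius profile. The
#' `cylinder` preset has near-constant width (chain `|K'|` of about 0.149
#' and 0.038, both inside the cylinder interval); the `tower` preset
#' widens toward the bottom (chain `|K'|` of about 0.467, inside the tower
#' interval).
#'
#' @param name `"cylinder"`, `"tower"`, or `"custom"` (requires
#'   `corners`).
#' @param corners For `"custom"`: a 2-column matrix/data frame of `(u, r)`
#'   corners, heights strictly decreasing, `r >= 0`, with a convex
#'   (monotone-slope) silhouette.
#' @return An object of class `plant_profile`: list with `name` and a
#'   `corners` tibble (`u`, `r`).
#' @examples
#' plant_profile("tower")
#' @export
plant_profile <- function(name = c("cylinder", "tower", "custom"),
                          corners = NULL) {
  name <- match.arg(name)
  if (name == "cylinder") {
    corners <- rbind(c(5.0, 0.72), c(4.9, 0.78), c(1.0, 0.80), c(0.5, 0.72))
  } else if (name == "tower") {
    corners <- rbind(c(5.0, 0.02), c(4.4, 1.30), c(0.5, 1.42))
  } else if (is.null(corners)) {
    abort("custom profile requires `corners`.")
  }
  m <- as.matrix(corners)
  if (ncol(m) != 2 || nrow(m) < 2 || anyNA(m)) {
    abort("`corners` must be an n x 2 matrix of (u, r) pairs, n >= 2.")
  }
  if (any(diff(m[, 1]) >= 0)) {
    abort("corner heights must be strictly decreasing top to bottom.")
  }
  if (any(m[, 2] < 0)) abort("half-widths must be >= 0.")
  if (!profile_is_convex(m)) {
    abort("profile silhouette is not convex (slope sequence not monotone).")
  }
  structure(list(name = name,
                 corners = tibble::tibble(u = m[, 1], r = m[, 2])),
            class = "plant_profile")
}

# right-chain slopes dY/dX (Y = lateral = r, X = vertical = u) must be
# non-decreasing going down for the revolved silhouette to be convex
profile_is_convex <- function(m, tol = 1e-12) {
  slopes <- diff(m[, 2]) / diff(m[, 1])
  all(diff(slopes) >= -tol)
}

#' @export
print.plant_profile <- function(x, ...) {
  cat("<plant_profile>", x$name, "with", nrow(x$corners), "corners\n")
  print(x$corners)
  invisible(x)
}

#' Corner change rates implied by a profile
#'
#' Evaluates `|K'|` along the profile's silhouette chain, optionally after
#' the same height normalization the analysis pipeline applies, and
#' derives the ground-truth label by the interval majority rule.
#'
#' @param profile A [plant_profile()].
#' @param normalize,target_height Match the pipeline normalization
#'   (default: scale the profile to vertical extent 5).
#' @param intervals [type_intervals()] used for the truth label.
#' @return A list with `rates` (numeric) and `label`.
#' @export
profile_rates <- function(profile, normalize = TRUE, target_height = 5,
                          intervals = type_intervals()) {
  m <- as.matrix(profile$corners)
  if (normalize) {
    s <- target_height / (max(m[, 1]) - min(m[, 1]))
    m <- cbind((m[, 1] - min(m[, 1])) * s, m[, 2] * s)
  }
  rates <- chain_rates(cbind(x = m[, 2], y = m[, 1]))$rate
  label <- if (length(rates) == 0) {
    "tower"
  } else {
    classify_plant(rates, intervals)$label
  }
  list(rates = rates, label = label)
}

#' Generate a synthetic plant point cloud from a profile
#'
#' Sweeps the piecewise-linear radius profile about the vertical axis:
#' rings are sampled at `rings` heights (always including every profile
#' corner height) with `azimuth_steps` equally spaced azimuths starting at
#' 0, so at the default 360 steps every 10-degree projection angle aligns
#' with sampled azimuths and the silhouette extremes are exact. Body
#' points get green-range colors. Optional imperfections emulate
#' reconstruction artifacts: inward-only radial noise (radius scaled by
#' `1 - |eps|`, `eps ~ N(0, radial_sigma)`, preserving the designed
#' silhouette), `n_black_edge` near-black points on the silhouette
#' surface, and `n_outliers` scattered uniformly in a 3x-inflated bounding
#' box. Deterministic given `seed`.
#'
#' @param profile A [plant_profile()].
#' @param rings Number of ring heights (>= number of profile corners).
#' @param azimuth_steps Points per ring (>= 8).
#' @param radial_sigma Inward-only radial noise fraction (>= 0).
#' @param n_outliers,n_black_edge Artifact point counts (>= 0).
#' @param seed Integer seed.
#' @return A list with `cloud` (point-cloud tibble) and `label` (ground
#'   truth from [profile_rates()]).
#' @export
generate_plant_cloud <- function(profile, rings = 40, azimuth_steps = 360,
                                 radial_sigma = 0, n_outliers = 0,
                                 n_black_edge = 0, seed = 1) {
  if (!inherits(profile, "plant_profile")) {
    abort("`profile` must be a plant_profile() object.")
  }
  m <- as.matrix(profile$corners)
  if (rings < nrow(m)) abort("`rings` must be >= the number of corners.")
  if (azimuth_steps < 8) abort("`azimuth_steps` must be >= 8.")
  if (radial_sigma < 0 || n_outliers < 0 || n_black_edge < 0) {
    abort("noise parameters must be >= 0.")
  }
  u_corners <- m[, 1]
  # exactly `rings` heights: an even grid whose interior points nearest to
  # each interior profile corner are snapped onto that corner height
  heights <- seq(max(u_corners), min(u_corners), length.out = rings)
  interior <- u_corners[u_corners > min(u_corners) & u_corners < max(u_corners)]
  avail <- setdiff(seq_len(rings), c(1L, rings))
  for (cu in interior) {
    i <- avail[which.min(abs(heights[avail] - cu))]
    heights[i] <- cu
    avail <- setdiff(avail, i)
  }
  heights <- sort(unique(heights), decreasing = TRUE)
  radius_at <- function(u) {
    stats::approx(rev(u_corners), rev(m[, 2]), xout = u, rule = 2)$y
  }
  withr::with_seed(seed, {
    u <- rep(heights, each = azimuth_steps)
    phi <- rep((seq_len(azimuth_steps) - 1) * 2 * pi / azimuth_steps,
               times = length(heights))
    r <- radius_at(u)
    if (radial_sigma > 0) {
      r <- pmax(0, r * (1 - abs(rnorm(length(r), 0, radial_sigma))))
    }
    body <- tibble::tibble(
      x = r * cos(phi), y = u, z = r * sin(phi),
      r = sample(60:120, length(u), replace = TRUE),
      g = sample(120:220, length(u), replace = TRUE),
      b = sample(50:110, length(u), replace = TRUE)
    )
    extra <- list()
    if (n_black_edge > 0) {
      ub <- runif(n_black_edge, min(u_corners), max(u_corners))
      pb <- runif(n_black_edge, 0, 2 * pi)
      rb <- radius_at(ub)
      extra$black <- tibble::tibble(
        x = rb * cos(pb), y = ub, z = rb * sin(pb),
        r = sample(0:40, n_black_edge, replace = TRUE),
        g = sample(0:40, n_black_edge, replace = TRUE),
        b = sample(0:40, n_black_edge, replace = TRUE)
      )
    }
    if (n_outliers > 0) {
      lo <- c(min(body$x), min(body$y), min(body$z))
      hi <- c(max(body$x), max(body$y), max(body$z))
      ctr <- (lo + hi) / 2
      half <- (hi - lo) / 2 * 3
      extra$outliers <- tibble::tibble(
        x = runif(n_outliers, ctr[1] - half[1], ctr[1] + half[1]),
        y = runif(n_outliers, ctr[2] - half[2], ctr[2] + half[2]),
        z = runif(n_outliers, ctr[3] - half[3], ctr[3] + half[3]),
        r = sample(60:120, n_outliers, replace = TRUE),
        g = sample(120:220, n_outliers, replace = TRUE),
        b = sample(50:110, n_outliers, replace = TRUE)
      )
    }
    cloud <- as_point_cloud(dplyr::bind_rows(c(list(body = body), extra)),
                            name = profile$name)
    list(cloud = cloud, label = profile_rates(profile)$label)
  })
}

# perturb corner half-widths by up to `jitter` (relative), resampling
# until the silhouette stays convex AND every designed corner still
# survives the pipeline's default chain simplification (otherwise the
# jitter would erase the architecture the truth label describes)
jitter_profile <- function(profile, jitter = 0.05, max_tries = 100,
                           simplify_tol = 0.05, target_height = 5) {
  m <- as.matrix(profile$corners)
  if (jitter == 0) return(profile)
  for (i in seq_len(max_tries)) {
    r2 <- m[, 2] * (1 + runif(nrow(m), -jitter, jitter))
    cand <- cbind(m[, 1], r2)
    if (profile_is_convex(cand) &&
        corners_survive_simplification(cand, simplify_tol, target_height)) {
      return(plant_profile("custom", corners = cand))
    }
  }
  warn("could not jitter profile within validity bounds; using preset.")
  profile
}

corners_survive_simplification <- function(m, tol, target_height) {
  s <- target_height / (max(m[, 1]) - min(m[, 1]))
  chain <- cbind(x = m[, 2] * s, y = (m[, 1] - min(m[, 1])) * s)
  nrow(simplify_chain(chain, tol)) == nrow(m)
}

#' Generate a labeled synthetic plant dataset
#'
#' Produces `n_cylinder + n_tower` plants from the two presets, each with
#' its corner half-widths independently perturbed by up to `jitter`
#' (convexity re-validated) and its own seed derived from `seed`.
#'
#' @param n_cylinder,n_tower Plant counts (>= 0).
#' @param jitter Relative half-width perturbation bound (default 0.05).
#' @inheritParams generate_plant_cloud
#' @return A tibble with columns `plant_id`, `label` (ground truth) and
#'   `cloud` (list column of point-cloud tibbles).
#' @export
generate_dataset <- function(n_cylinder, n_tower, rings = 40,
                             azimuth_steps = 360, radial_sigma = 0,
                             n_outliers = 0, n_black_edge = 0,
                             jitter = 0.05, seed = 1) {
  if (n_cylinder < 0 || n_tower < 0) abort("counts must be >= 0.")
  n <- n_cylinder + n_tower
  empty <- tibble::tibble(plant_id = character(), label = character(),
                          cloud = list())
  if (n == 0) return(empty)
  presets <- c(rep("cylinder", n_cylinder), rep("tower", n_tower))
  plant_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  purrr::map_dfr(seq_len(n), function(i) {
    prof <- withr::with_seed(
      plant_seeds[i], jitter_profile(plant_profile(presets[i]), jitter))
    gen <- generate_plant_cloud(prof, rings = rings,
                                azimuth_steps = azimuth_steps,
                                radial_sigma = radial_sigma,
                                n_outliers = n_outliers,
                                n_black_edge = n_black_edge,
                                seed = plant_seeds[i])
    tibble::tibble(plant_id = sprintf("%s_%02d", presets[i], i),
                   label = gen$label, cloud = list(gen$cloud))
  })
}
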