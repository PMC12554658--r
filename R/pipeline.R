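# End-to-end workflow: configuration, per-plant classification pipeline
# (read -> orient -> denoise -> down-sample -> project -> hull/rates ->
# classify), and evaluation against truth labels. A thin command-line
# wrapper over these functions ships in inst/scripts/planthull.R.

#' Pipeline configuration
#'
#' Bundles every tunable stage parameter with validated defaults. Set
#' `denoise = FALSE` to skip the two filters (e.g. for clean synthetic
#' clouds), `voxel_leaf = 0` to skip down-sampling, `orient = FALSE` to
#' trust the input coordinate frame.
#'
#' @param stat_k,stat_std_mult Statistical outlier filter parameters
#'   ([filter_statistical_outliers()]).
#' @param color_min,color_max Color keep band ([filter_color()]).
#' @param voxel_leaf Voxel edge ([downsample_voxel()]); `NULL` = 2% of the
#'   bounding-box diagonal, `0` = skip.
#' @param step_deg Projection angular step ([project_views()]).
#' @param target_height View normalization height ([normalize_view()]).
#' @param simplify_tol Chain simplification tolerance ([simplify_chain()]).
#' @param intervals [type_intervals()] for classification.
#' @param orient,denoise Stage switches.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stat_k = 30, stat_std_mult = 1,
                            color_min = c(41, 41, 41),
                            color_max = c(255, 255, 255),
                            voxel_leaf = NULL, step_deg = 10,
                            target_height = 5, simplify_tol = 0.05,
                            intervals = type_intervals(),
                            orient = TRUE, denoise = TRUE) {
  cfg <- list(stat_k = stat_k, stat_std_mult = stat_std_mult,
              color_min = color_min, color_max = color_max,
              voxel_leaf = voxel_leaf, step_deg = step_deg,
              target_height = target_height, simplify_tol = simplify_tol,
              intervals = intervals, orient = isTRUE(orient),
              denoise = isTRUE(denoise))
  if (!inherits(cfg$intervals, "type_intervals")) {
    abort("`intervals` must be a type_intervals() object.")
  }
  if (cfg$step_deg <= 0 || cfg$step_deg > 180 ||
      abs(360 / cfg$step_deg - round(360 / cfg$step_deg)) > 1e-9) {
    abort("`step_deg` must divide 360 and lie in (0, 180].")
  }
  if (cfg$target_height <= 0) abort("`target_height` must be > 0.")
  if (cfg$simplify_tol < 0) abort("`simplify_tol` must be >= 0.")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `stat_filter: {k, std_mult}`, `color_filter:
#' {min_rgb, max_rgb}`, `voxel: {leaf}`, `projection: {step_deg,
#' target_height}`, `hull: {simplify_tol}`, `intervals: {cylinder,
#' tower}`, `orient`, `denoise`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("stat_filter", "color_filter", "voxel", "projection", "hull",
             "intervals", "orient", "denoise")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  gv <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  iv <- raw$intervals
  pipeline_config(
    stat_k = gv("stat_filter", "k", 30),
    stat_std_mult = gv("stat_filter", "std_mult", 1),
    color_min = unlist(gv("color_filter", "min_rgb", c(41, 41, 41))),
    color_max = unlist(gv("color_filter", "max_rgb", c(255, 255, 255))),
    voxel_leaf = gv("voxel", "leaf", NULL),
    step_deg = gv("projection", "step_deg", 10),
    target_height = gv("projection", "target_height", 5),
    simplify_tol = gv("hull", "simplify_tol", 0.05),
    intervals = type_intervals(
      cylinder = unlist(if (is.null(iv$cylinder)) c(0, 0.2) else iv$cylinder),
      tower = unlist(if (is.null(iv$tower)) c(0.4, 1.5) else iv$tower)),
    orient = if (is.null(raw$orient)) TRUE else raw$orient,
    denoise = if (is.null(raw$denoise)) TRUE else raw$denoise
  )
}

classify_one <- function(cloud, config, verbose = FALSE) {
  say <- function(stage, n) {
    if (verbose) message(sprintf("  %-22s %d points", stage, n))
  }
  say("input", nrow(cloud))
  if (config$orient) cloud <- orient_plant(cloud)
  if (config$denoise) {
    cloud <- filter_statistical_outliers(cloud, k = config$stat_k,
                                         std_mult = config$stat_std_mult)
    say("statistical filter", nrow(cloud))
    cloud <- filter_color(cloud, config$color_min, config$color_max)
    say("color filter", nrow(cloud))
  }
  if (is.null(config$voxel_leaf) || config$voxel_leaf > 0) {
    cloud <- downsample_voxel(cloud, leaf = config$voxel_leaf)
    say("voxel down-sample", nrow(cloud))
  }
  views <- project_views(cloud, step_deg = config$step_deg)
  samples <- plant_rate_profile(views, simplify_tol = config$simplify_tol,
                                normalize = TRUE,
                                target_height = config$target_height)
  classify_plant(samples, config$intervals)
}

#' Classify plants end to end
#'
#' Runs the full identification pipeline on each input: read (if a path),
#' orient upright, statistical + color denoising, voxel down-sampling,
#' rotational projection, per-view hull/chain corner-change rates, and
#' interval classification.
#'
#' @param inputs A character vector of point-cloud file paths, a list of
#'   point-cloud tibbles, or a dataset tibble from [generate_dataset()]
#'   (columns `plant_id`, `cloud`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes `report.json` (per-plant
#'   counts and labels plus the intervals used) and one
#'   `<plant_id>_rates.csv` rate profile per plant.
#' @param verbose Log per-stage point counts.
#' @return A tibble with one row per plant: `plant_id`, `label`,
#'   `n_cylinder`, `n_tower`, `n_samples`; the full `plant_type` objects
#'   are in the `"results"` attribute. Unreadable inputs are recorded as
#'   `NA` rows with a warning; an error is raised if every input fails.
#' @export
classify_plants <- function(inputs, config = pipeline_config(),
                            out_dir = NULL, verbose = FALSE) {
  if (is.data.frame(inputs)) {
    ids <- inputs$plant_id
    clouds <- inputs$cloud
  } else if (is.character(inputs)) {
    if (length(inputs) == 0) abort("no input files given.")
    ids <- sub("\\.[^.]*$", "", basename(inputs))
    clouds <- as.list(inputs)
  } else if (is.list(inputs)) {
    clouds <- inputs
    ids <- if (!is.null(names(inputs))) names(inputs) else
      sprintf("plant_%02d", seq_along(inputs))
  } else {
    abort("`inputs` must be file paths, clouds, or a dataset tibble.")
  }
  if (length(clouds) == 0) abort("no inputs given.")
  results <- vector("list", length(clouds))
  rows <- purrr::map_dfr(seq_along(clouds), function(i) {
    res <- tryCatch({
      cl <- clouds[[i]]
      if (is.character(cl)) cl <- read_point_cloud(cl)
      if (verbose) message("plant ", ids[i], ":")
      classify_one(cl, config, verbose = verbose)
    }, error = function(e) {
      warn(paste0("plant '", ids[i], "' failed: ", conditionMessage(e)))
      NULL
    })
    results[[i]] <<- res
    if (is.null(res)) {
      tibble::tibble(plant_id = ids[i], label = NA_character_,
                     n_cylinder = NA_integer_, n_tower = NA_integer_,
                     n_samples = NA_integer_)
    } else {
      tibble::tibble(plant_id = ids[i], label = res$label,
                     n_cylinder = res$n_cylinder, n_tower = res$n_tower,
                     n_samples = nrow(res$samples))
    }
  })
  if (all(is.na(rows$label))) abort("all inputs failed to classify.")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(intervals = unclass(config$intervals),
           plants = rows),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    for (i in seq_along(results)) {
      if (!is.null(results[[i]])) {
        utils::write.csv(results[[i]]$samples,
                         file.path(out_dir, paste0(ids[i], "_rates.csv")),
                         row.names = FALSE)
      }
    }
  }
  attr(rows, "results") <- results
  rows
}

#' Evaluate predictions against truth labels
#'
#' Joins truth and predicted labels by `plant_id` and reports per-class
#' precision/recall (each class in turn as the positive one) with the
#' shared overall accuracy.
#'
#' @param truth,predicted Data frames with columns `plant_id` and `label`
#'   (a [classify_plants()] result works directly as `predicted`). `truth`
#'   may also be a CSV path.
#' @return A tibble with one row per class: `positive`, `accuracy`,
#'   `precision`, `recall`.
#' @export
evaluate_predictions <- function(truth, predicted) {
  if (is.character(truth)) truth <- utils::read.csv(truth)
  if (is.character(predicted)) predicted <- utils::read.csv(predicted)
  for (d in list(truth, predicted)) {
    if (!all(c("plant_id", "label") %in% names(d))) {
      abort("need columns `plant_id` and `label` in truth and predicted.")
    }
  }
  miss_t <- setdiff(predicted$plant_id, truth$plant_id)
  miss_p <- setdiff(truth$plant_id, predicted$plant_id)
  if (length(miss_t) > 0 || length(miss_p) > 0) {
    abort(paste0("plant_id mismatch; missing from truth: ",
                 paste(miss_t, collapse = ", "), "; missing from predicted: ",
                 paste(miss_p, collapse = ", ")))
  }
  merged <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(truth[, c("plant_id", "label")]),
                  truth = "label"),
    dplyr::rename(tibble::as_tibble(predicted[, c("plant_id", "label")]),
                  predicted = "label"),
    by = "plant_id")
  if (anyNA(merged$predicted)) {
    warn(paste0(sum(is.na(merged$predicted)),
                " plant(s) without a prediction dropped from evaluation."))
    merged <- merged[!is.na(merged$predicted), ]
  }
  if (nrow(merged) == 0) abort("no evaluable (truth, prediction) pairs.")
  classes <- sort(unique(c(merged$truth, merged$predicted)))
  purrr::map_dfr(classes, function(cl) {
    met <- classification_metrics(
      confusion_counts(merged$truth, merged$predicted, positive = cl))
    dplyr::mutate(met, positive = cl, .before = 1)
  })
}
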