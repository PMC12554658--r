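# Evaluation toolkit: RMSE, confusion metrics, inter-rater agreement,
# Welch's test, and seeded k-fold cross-validation of the interval
# classifier.

#' Root mean square error
#'
#' @param predicted,truth Equal-length nonempty numeric vectors.
#' @return `sqrt(mean((predicted - truth)^2))`.
#' @export
rmse <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) == 0) {
    abort("`predicted` and `truth` must be nonempty and of equal length.")
  }
  sqrt(mean((as.double(predicted) - as.double(truth))^2))
}

#' Confusion counts from label vectors
#'
#' @param truth,predicted Equal-length nonempty label vectors.
#' @param positive The label treated as the positive class.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c("a", "b"), c("a", "a"), positive = "a")
#' @export
confusion_counts <- function(truth, predicted, positive = "cylinder") {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    abort("`truth` and `predicted` must be nonempty and of equal length.")
  }
  t_pos <- truth == positive
  p_pos <- predicted == positive
  tibble::tibble(
    tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
    fn = sum(t_pos & !p_pos), tn = sum(!t_pos & !p_pos)
  )
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`, `precision = TP / (TP +
#' FP)`, `recall = TP / (TP + FN)`. A zero denominator yields `NA` for the
#' affected metric with a warning. Full-precision values are returned;
#' report formatting truncates to 2 decimals (see [format_metrics()]).
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `fn`, `tn`
#'   (see [confusion_counts()]).
#' @return A one-row tibble with `accuracy`, `precision`, `recall`.
#' @export
classification_metrics <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts)) || nrow(counts) != 1) {
    abort("`counts` must be a one-row data frame with tp, fp, fn, tn.")
  }
  cnt <- lapply(counts[need], as.double)
  if (any(unlist(cnt) < 0)) abort("counts must be nonnegative.")
  total <- cnt$tp + cnt$fp + cnt$fn + cnt$tn
  if (total == 0) abort("all counts are zero.")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined: zero denominator."))
      return(NA_real_)
    }
    num / den
  }
  tibble::tibble(
    accuracy = (cnt$tp + cnt$tn) / total,
    precision = safe_div(cnt$tp, cnt$tp + cnt$fp, "precision"),
    recall = safe_div(cnt$tp, cnt$tp + cnt$fn, "recall")
  )
}

#' Format metric values for reports
#'
#' Truncates toward zero to 2 decimals (0.727... prints as 0.72), the
#' convention used in console/report output; raw full-precision values are
#' always kept in returned objects.
#'
#' @param x Numeric metric values.
#' @return Character vector of truncated 2-decimal representations.
#' @export
format_metrics <- function(x) sprintf("%.2f", trunc(x * 100) / 100)

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning categorical labels
#' to `N` subjects; 1 for perfect agreement. Undefined (error) when every
#' rating is a single identical category, since expected agreement is then
#' 1.
#'
#' @param ratings A subjects x raters matrix/data frame of categorical
#'   labels (at least 2 subjects and 2 raters).
#' @return Kappa (numeric scalar, `<= 1`).
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2 || ncol(m) < 2 || anyNA(m)) {
    abort("`ratings` must be a complete subjects x raters matrix (>= 2 x 2).")
  }
  n_rat <- ncol(m)
  cats <- sort(unique(as.vector(m)))
  counts <- t(apply(m, 1, function(row) {
    as.double(table(factor(row, levels = cats)))
  }))
  if (length(cats) == 1) counts <- matrix(counts, ncol = 1)
  p_j <- colSums(counts) / sum(counts)
  pe <- sum(p_j^2)
  if (1 - pe < .Machine$double.eps) {
    abort("kappa undefined: a single category across all ratings.")
  }
  p_i <- (rowSums(counts^2) - n_rat) / (n_rat * (n_rat - 1))
  (mean(p_i) - pe) / (1 - pe)
}

#' Cohen's kappa for two raters
#'
#' @param rater1,rater2 Equal-length label vectors.
#' @return Kappa (numeric scalar).
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2) || length(rater1) < 2) {
    abort("need two equal-length label vectors (n >= 2).")
  }
  cats <- sort(unique(c(rater1, rater2)))
  f1 <- factor(rater1, levels = cats)
  f2 <- factor(rater2, levels = cats)
  tab <- table(f1, f2) / length(rater1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) {
    abort("kappa undefined: a single category across all ratings.")
  }
  (po - pe) / (1 - pe)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test of equal means, used to test whether the corner change
#' rates of the two plant types differ. Thin wrapper over
#' [stats::t.test()] returning a tidy row.
#'
#' @param sample_a,sample_b Numeric samples, each `n >= 2`, with nonzero
#'   variance in at least one.
#' @return One-row tibble with `statistic` (t), `df`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs n >= 2.")
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    abort("both samples have zero variance; the test is undefined.")
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Seeded k-fold cross-validation of the interval classifier
#'
#' Shuffles plants with the given seed, splits them into `k` contiguous
#' near-equal folds, and for each fold fits classification intervals on
#' the remaining folds ([fit_intervals()]), classifies each held-out
#' plant's pooled rate samples ([classify_plant()]), and scores the fold
#' (cylinder as the positive class). Deterministic given `seed`.
#'
#' @param plant_rates A tibble with columns `plant_id`, `label` (truth)
#'   and `rate`, several rate samples per plant.
#' @param k Number of folds (`2 <= k <=` number of plants).
#' @param seed Integer seed for the fold shuffle.
#' @param method Interval aggregation method passed to [fit_intervals()].
#' @return A tibble with one row per fold: `fold`, `n_test`, `accuracy`,
#'   `precision`, `recall`.
#' @export
kfold_cross_validate <- function(plant_rates, k = 5, seed = 1,
                                 method = "minmax") {
  need <- c("plant_id", "label", "rate")
  if (!all(need %in% names(plant_rates))) {
    abort("`plant_rates` must have columns plant_id, label, rate.")
  }
  plants <- dplyr::distinct(plant_rates[, c("plant_id", "label")])
  if (any(duplicated(plants$plant_id))) {
    abort("each plant_id must carry a single truth label.")
  }
  n <- nrow(plants)
  k <- as.integer(k)
  if (k < 2 || k > n) abort("`k` must be in [2, number of plants].")
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), times = sizes)
  assignment <- tibble::tibble(plant_id = plants$plant_id[perm],
                               fold = fold_of)
  purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- assignment$plant_id[assignment$fold == f]
    train <- plant_rates[!plant_rates$plant_id %in% test_ids, ]
    fitted <- fit_intervals(train[, c("label", "rate")], method = method)
    test <- plant_rates[plant_rates$plant_id %in% test_ids, ]
    pred <- purrr::map_chr(split(test, test$plant_id), function(d) {
      classify_plant(d$rate, fitted)$label
    })
    truth <- plants$label[match(names(pred), plants$plant_id)]
    met <- classification_metrics(
      confusion_counts(truth, pred, positive = "cylinder"))
    dplyr::mutate(met, fold = f, n_test = length(pred), .before = 1)
  })
}
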