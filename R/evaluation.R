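#' Per-class and aggregate classification metrics
#'
#' One-vs-rest contingency counts per grade with precision, recall,
#' F1-score and per-class accuracy, plus a `Total` row holding the
#' unweighted macro-average of the per-class columns (weighted averaging by
#' class support is available via `average`). The overall multi-class
#' accuracy (correct/total) is attached as the `accuracy` attribute and in
#' the `Total` row's `accuracy` column. Abstained images must be removed by
#' the caller before computing metrics. Zero-division cells (e.g. precision
#' of a never-predicted class) yield 0 and set the `zero_division` flag.
#'
#' @param truths,predictions Integer class labels in 1..n_classes, equal
#'   length.
#' @param n_classes Number of classes `c`.
#' @param average `"macro"` (unweighted, default) or `"weighted"` (by class
#'   support) for the `Total` row.
#' @return A tibble of class `grading_metrics` with columns `grade`, `tp`,
#'   `fp`, `fn`, `tn`, `precision`, `recall`, `f1`, `accuracy`,
#'   `zero_division`; attributes `confusion` (c x c count matrix,
#'   truth x prediction) and `accuracy` (overall).
#' @export
classification_metrics <- function(truths, predictions, n_classes,
                                   average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (length(truths) != length(predictions)) {
    stop_contract("`truths` and `predictions` differ in length (%d vs %d)",
                  length(truths), length(predictions))
  }
  if (!is_count(n_classes, min = 2L)) {
    stop_parameter("`n_classes` must be an integer >= 2")
  }
  lv <- seq_len(n_classes)
  if (!all(truths %in% lv) || !all(predictions %in% lv)) {
    stop_contract("labels must be integers in 1..%d", n_classes)
  }
  conf <- table(factor(truths, levels = lv), factor(predictions, levels = lv))
  conf <- matrix(as.integer(conf), n_classes, n_classes,
                 dimnames = list(truth = lv, prediction = lv))
  total <- sum(conf)
  per <- purrr::map(lv, function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    tn <- total - tp - fp - fn
    zd <- FALSE
    prec <- if (tp + fp > 0) tp / (tp + fp) else { zd <- TRUE; 0 }
    rec  <- if (tp + fn > 0) tp / (tp + fn) else { zd <- TRUE; 0 }
    f1   <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else { zd <- TRUE; 0 }
    tibble(grade = as.character(k), tp = tp, fp = fp, fn = fn, tn = tn,
           precision = prec, recall = rec, f1 = f1,
           accuracy = (tp + tn) / total, zero_division = zd)
  }) |> dplyr::bind_rows()
  if (any(per$zero_division)) {
    warn("zero-division in per-class metrics; affected values reported as 0")
  }
  wts <- if (average == "macro") rep(1 / n_classes, n_classes) else {
    support <- rowSums(conf)
    support / sum(support)
  }
  overall <- sum(diag(conf)) / total
  tot <- tibble(grade = "Total",
                tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
                tn = sum(per$tn),
                precision = sum(per$precision * wts),
                recall = sum(per$recall * wts),
                f1 = sum(per$f1 * wts),
                accuracy = overall,
                zero_division = any(per$zero_division))
  out <- dplyr::bind_rows(per, tot)
  structure(out, confusion = conf, accuracy = overall, average = average,
            class = c("grading_metrics", class(out)))
}

#' Summarize elastic grading per cross-validation fold
#'
#' For each fold, counts the included images `d_i` (graded, not abstained),
#' the excluded images `R_i` (abstained), the correctly graded ones, and
#' the fold accuracy on included images only. Folds with `d_i = 0` carry an
#' `NA` accuracy and an `undefined` flag.
#'
#' @param graded A tibble with columns `image_id`, `grade` (`NA` =
#'   abstained), `abstained`, `truth`, `fold`.
#' @return A tibble of class `fold_outcomes`: `fold`, `n_included`,
#'   `n_excluded`, `n_correct`, `accuracy`, `undefined`.
#' @export
fold_outcomes <- function(graded) {
  req <- c("grade", "abstained", "truth", "fold")
  if (!all(req %in% names(graded))) {
    stop_contract("`graded` needs columns %s", paste(req, collapse = ", "))
  }
  out <- graded |>
    dplyr::group_by(fold = .data$fold) |>
    dplyr::summarise(
      n_included = sum(!.data$abstained),
      n_excluded = sum(.data$abstained),
      n_correct = sum(!.data$abstained & .data$grade == .data$truth,
                      na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      accuracy = ifelse(.data$n_included > 0,
                        .data$n_correct / .data$n_included, NA_real_),
      undefined = .data$n_included == 0)
  structure(out, class = c("fold_outcomes", class(out)))
}

#' Weighted average accuracy over included images
#'
#' \deqn{WAA = \frac{\sum_i Accuracy_i \, d_i}{\sum_i d_i}}
#' the fold accuracies on included (non-abstained) images weighted by the
#' included-image counts `d_i`. Folds with no included images contribute
#' nothing. When no image is abstained anywhere, WAA equals the pooled
#' accuracy over all test images.
#'
#' @param folds A [fold_outcomes()] tibble.
#' @return WAA as a fraction in `[0, 1]`.
#' @export
waa <- function(folds) {
  d <- folds$n_included
  if (sum(d) == 0) {
    abort("WAA undefined: every fold abstained on every image",
          class = "elasticgrade_undefined_error")
  }
  sum(folds$accuracy[d > 0] * d[d > 0]) / sum(d)
}

#' Abstain percentage
#'
#' \deqn{AP = \frac{\sum_i R_i}{DS} \times 100}
#' the excluded (abstained) images across folds as a percentage of the
#' dataset size `DS`.
#'
#' @param folds A [fold_outcomes()] tibble.
#' @param dataset_size Total number of images `DS` across all folds.
#' @return AP in percent, `[0, 100]`.
#' @export
ap <- function(folds, dataset_size) {
  if (!is_count(dataset_size)) {
    stop_parameter("`dataset_size` must be a positive integer")
  }
  if (sum(folds$n_included + folds$n_excluded) != dataset_size) {
    stop_contract("fold counts sum to %d, not dataset_size = %d",
                  sum(folds$n_included + folds$n_excluded), dataset_size)
  }
  100 * sum(folds$n_excluded) / dataset_size
}

#' Stratified k-fold split of a labeled manifest
#'
#' Assigns each image to one of `k` disjoint, exhaustive test folds,
#' stratified by grade so every fold sees every grade in near-equal
#' proportion. Deterministic given `seed`. If any grade has fewer than `k`
#' images, stratification is impossible and the split falls back to an
#' unstratified shuffle with a warning.
#'
#' @param manifest A data frame with at least `image_id` and `grade`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffles.
#' @return The manifest as a tibble with an integer `fold` column (1..k).
#' @export
crossval_split <- function(manifest, k = 5L, seed = 1L) {
  if (!is_count(k, min = 2L)) stop_parameter("`k` must be an integer >= 2")
  if (k > nrow(manifest)) stop_parameter("`k` exceeds the number of images")
  manifest <- as_tibble(manifest)
  counts <- table(manifest$grade)
  stratify <- all(counts >= k)
  if (!stratify) {
    warn(sprintf("grade(s) %s have fewer than k = %d images; falling back to an unstratified split",
                 paste(names(counts)[counts < k], collapse = ", "), k))
  }
  with_seed(seed, {
    if (stratify) {
      manifest |>
        dplyr::group_by(.data$grade) |>
        dplyr::mutate(fold = sample(rep_len(seq_len(k), dplyr::n()))) |>
        dplyr::ungroup()
    } else {
      dplyr::mutate(manifest, fold = sample(rep_len(seq_len(k), dplyr::n())))
    }
  })
}

#' Evaluate elastic grading under cross-validation
#'
#' Joins per-image elastic grades with the manifest truth and folds, and
#' assembles the full evaluation report: per-class metrics over the
#' non-abstained images, the confusion matrix, fold outcomes, WAA and AP.
#'
#' @param graded A [grade_from_predictions()] table (or any tibble with
#'   `image_id`, `grade`, `abstained`).
#' @param manifest A tibble with `image_id`, `grade` (truth) and `fold`
#'   (from [crossval_split()]).
#' @param n_classes Number of grade classes.
#' @param beta The threshold the grades were produced with (recorded in the
#'   report).
#' @return An object of class `elastic_eval`: list with `metrics`
#'   ([classification_metrics()] tibble, `NULL` if everything abstained),
#'   `folds` ([fold_outcomes()]), `waa`, `ap`, `accuracy`, `dataset_size`,
#'   `n_classes`, `beta`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
evaluate_folds <- function(graded, manifest, n_classes = 3L, beta = NA_real_) {
  joined <- dplyr::inner_join(
    dplyr::select(graded, "image_id", "grade", "abstained"),
    dplyr::select(as_tibble(manifest), "image_id", truth = "grade", "fold"),
    by = "image_id")
  if (nrow(joined) != nrow(graded)) {
    stop_contract("%d graded image(s) missing from the manifest",
                  nrow(graded) - nrow(joined))
  }
  folds <- fold_outcomes(joined)
  included <- dplyr::filter(joined, !.data$abstained)
  metrics <- if (nrow(included) > 0) {
    classification_metrics(included$truth, included$grade, n_classes)
  } else NULL
  w <- if (sum(folds$n_included) > 0) waa(folds) else NA_real_
  structure(list(metrics = metrics, folds = folds, waa = w,
                 ap = ap(folds, nrow(joined)),
                 accuracy = if (is.null(metrics)) NA_real_ else attr(metrics, "accuracy"),
                 dataset_size = nrow(joined), n_classes = n_classes,
                 beta = beta),
            class = "elastic_eval")
}

#' @export
print.elastic_eval <- function(x, ...) {
  cat(sprintf("<elastic_eval> %d images, %d folds, beta = %s bits\n",
              x$dataset_size, nrow(x$folds),
              ifelse(is.na(x$beta), "?", format(x$beta))))
  cat(sprintf("  WAA %.4f | AP %.2f%% | accuracy (included) %.4f\n",
              x$waa, x$ap, x$accuracy))
  invisible(x)
}

#' Sweep the entropy threshold over cached predictions
#'
#' Re-gates a cached per-member prediction table at each `beta` (members are
#' never re-run), evaluates each threshold under the given folds, and
#' returns the coverage-accuracy trade-off curve. Because selections are
#' nested in `beta`, the abstain percentage is non-increasing as `beta`
#' grows; this is asserted on the result. Rows are returned in ascending
#' `beta`.
#'
#' @param predictions Cached [predict_members()] table over all images.
#' @param betas Numeric vector of thresholds in bits (non-empty).
#' @param manifest Tibble with `image_id`, `grade`, `fold`.
#' @param n_classes Number of grade classes.
#' @param vote Aggregation rule.
#' @return A tibble of class `beta_sweep`: `beta`, `waa`, `ap`,
#'   `n_included`, `n_excluded`.
#' @export
beta_sweep <- function(predictions, betas, manifest, n_classes = 3L,
                       vote = "soft") {
  if (length(betas) == 0L || !is.numeric(betas)) {
    stop_parameter("`betas` must be a non-empty numeric vector")
  }
  betas <- sort(unique(betas))
  rows <- purrr::map(betas, function(b) {
    graded <- grade_from_predictions(predictions, b, vote)
    ev <- evaluate_folds(graded, manifest, n_classes, beta = b)
    tibble(beta = b, waa = ev$waa, ap = ev$ap,
           n_included = sum(ev$folds$n_included),
           n_excluded = sum(ev$folds$n_excluded))
  })
  out <- dplyr::bind_rows(rows)
  if (is.unsorted(rev(out$ap))) {
    stop_contract("abstain percentage increased with beta; gating is inconsistent")
  }
  structure(out, class = c("beta_sweep", class(out)))
}

#' Default threshold grid for beta sweeps
#'
#' 25 log-spaced values in `[1e-8, 1]` plus the linear tail
#' `{1.25, 1.5, 1.75, 2}`, covering the operating range commonly explored
#' for 3-class grading (the maximum possible entropy is `log2(3) ~ 1.585`
#' bits, so the tail reaches full coverage).
#'
#' @return A sorted numeric vector of thresholds in bits.
#' @export
default_beta_grid <- function() {
  c(10^seq(-8, 0, length.out = 25), 1.25, 1.5, 1.75, 2)
}
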