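#' Tidy an elastic evaluation into per-class metrics
#'
#' @param x An [evaluate_folds()] result.
#' @param ... Unused.
#' @return A tibble with one row per grade plus the `Total` macro-average
#'   row: `grade`, `precision`, `recall`, `f1`, `accuracy`.
#' @export
tidy.elastic_eval <- function(x, ...) {
  if (is.null(x$metrics)) {
    return(tibble(grade = character(0), precision = double(0),
                  recall = double(0), f1 = double(0), accuracy = double(0)))
  }
  dplyr::select(as_tibble(x$metrics), "grade", "precision", "recall",
                "f1", "accuracy")
}

#' One-row summary of an elastic evaluation
#'
#' @param x An [evaluate_folds()] result.
#' @param ... Unused.
#' @return A one-row tibble: `beta`, `waa`, `ap`, `accuracy`,
#'   `n_included`, `n_excluded`, `dataset_size`, `n_folds`.
#' @export
glance.elastic_eval <- function(x, ...) {
  tibble(beta = x$beta, waa = x$waa, ap = x$ap, accuracy = x$accuracy,
         n_included = sum(x$folds$n_included),
         n_excluded = sum(x$folds$n_excluded),
         dataset_size = x$dataset_size, n_folds = nrow(x$folds))
}

#' Tidy per-fold outcomes of an elastic evaluation
#'
#' @param x A [fold_outcomes()] tibble.
#' @param ... Unused.
#' @return The fold table as a plain tibble.
#' @export
tidy.fold_outcomes <- function(x, ...) as_tibble(unclass(x))
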