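#' Shannon entropy of a class-probability vector, in bits
#'
#' \eqn{H(X) = -\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \cdot \log_2 0 = 0}, so a one-hot vector has exactly zero entropy
#' (no epsilon flooring). The result lies in `[0, log2(c)]` for `c` classes.
#' Entropy in bits is the per-member uncertainty measure the elastic gate
#' compares against the threshold `beta`.
#'
#' @param p Probability vector (entries >= 0, summing to 1 within 1e-6).
#' @return Entropy in bits (scalar).
#' @examples
#' shannon_entropy(c(1, 0, 0))        # 0
#' shannon_entropy(c(0.5, 0.5, 0))    # 1
#' shannon_entropy(rep(1 / 3, 3))     # log2(3)
#' @export
shannon_entropy <- function(p) {
  check_prob_vector(p)
  p <- pmax(p, 0)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Tabulate member predictions with their entropies
#'
#' Runs every member on a feature grid and collects the per-member
#' probability vectors and Shannon entropies into the tidy prediction table
#' used by the gate, the sweep and the evaluators.
#'
#' @param members List of [member_model()] objects.
#' @param grid A [feature_grid()].
#' @param failure_policy `"skip"` logs a failing member and drops it (it can
#'   then never be selected); `"stop"` re-raises the error.
#' @return A tibble with columns `image_id`, `member_id`, `probs`
#'   (list-column), `entropy_bits`.
#' @export
predict_members <- function(members, grid, failure_policy = c("skip", "stop")) {
  failure_policy <- match.arg(failure_policy)
  stopifnot(length(members) > 0L)
  image_id <- attr(grid, "image_id")
  rows <- purrr::map(members, function(m) {
    p <- tryCatch(member_predict(m, grid), error = function(e) {
      if (failure_policy == "stop") stop(e)
      warn(sprintf("member '%s' failed on image '%s' (%s); treated as not selected",
                   m$member_id, image_id, conditionMessage(e)))
      NULL
    })
    if (is.null(p)) return(NULL)
    tibble(image_id = image_id, member_id = m$member_id,
           probs = list(p), entropy_bits = shannon_entropy(p))
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Select the members whose entropy beats the threshold
#'
#' A member is selected for an image exactly when the Shannon entropy of its
#' probability vector is *strictly below* `beta` (in bits). Input order is
#' preserved; an empty selection is a valid outcome and signals abstention.
#' Selections are nested in `beta`: raising the threshold never drops a
#' member.
#'
#' @param predictions A [predict_members()] table for one image.
#' @param beta Entropy threshold in bits (> 0). Values above `log2(c)` admit
#'   every member.
#' @return Character vector of selected `member_id`s.
#' @export
select_members <- function(predictions, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop_parameter("`beta` must be a single positive number")
  }
  if (nrow(predictions) == 0L) return(character(0))
  predictions$member_id[predictions$entropy_bits < beta]
}

#' Aggregate selected members by soft voting
#'
#' Arithmetic mean of the selected members' probability vectors,
#' renormalized to sum to one. With `vote = "majority"`, each selected
#' member instead casts one vote for its argmax class and the returned
#' vector is the normalized vote count (ties inherit the argmax rule:
#' lowest class index).
#'
#' @param predictions A [predict_members()] table for one image.
#' @param selected Character vector of member ids to aggregate (non-empty,
#'   all present in `predictions`).
#' @param vote `"soft"` (default, mean of distributions) or `"majority"`.
#' @return A probability vector.
#' @export
aggregate_members <- function(predictions, selected, vote = c("soft", "majority")) {
  vote <- match.arg(vote)
  if (length(selected) == 0L) {
    stop_contract("empty selection: abstention must be handled by the caller")
  }
  if (!all(selected %in% predictions$member_id)) {
    stop_contract("selected ids missing from predictions: %s",
                  paste(setdiff(selected, predictions$member_id), collapse = ", "))
  }
  probs <- predictions$probs[match(selected, predictions$member_id)]
  if (vote == "soft") {
    avg <- Reduce(`+`, probs) / length(probs)
  } else {
    c_n <- length(probs[[1]])
    votes <- tabulate(purrr::map_int(probs, which.max), nbins = c_n)
    avg <- votes
  }
  avg / sum(avg)
}

#' Grade one image with the elastic ensemble
#'
#' The full per-image procedure: every member predicts, entropies are
#' computed, members are gated by `beta`, and the survivors' distributions
#' are aggregated into the final grade (argmax, ties broken toward the
#' lowest class index). If no member passes the gate the image is
#' *abstained* — flagged for manual expert review rather than force-graded.
#'
#' @param members List of [member_model()] objects.
#' @param grid A [feature_grid()].
#' @param beta Entropy threshold in bits.
#' @param vote Aggregation rule, see [aggregate_members()].
#' @param failure_policy See [predict_members()].
#' @return An `elastic_result`: list with `image_id`, `beta`,
#'   `predictions` (the per-member table), `selected_member_ids`,
#'   `n_selected`, `aggregated` (probability vector, or `NULL` when
#'   abstained), `grade` (integer class 1..c, or `NA` when abstained) and
#'   `abstained` (logical).
#' @export
grade_image <- function(members, grid, beta, vote = "soft",
                        failure_policy = "skip") {
  preds <- predict_members(members, grid, failure_policy)
  sel <- select_members(preds, beta)
  if (length(sel) == 0L) {
    agg <- NULL
    grade <- NA_integer_
  } else {
    agg <- aggregate_members(preds, sel, vote)
    grade <- which.max(agg)  # which.max returns the first (lowest) maximum
  }
  structure(list(image_id = attr(grid, "image_id"), beta = beta,
                 predictions = preds, selected_member_ids = sel,
                 n_selected = length(sel), aggregated = agg,
                 grade = as.integer(grade), abstained = length(sel) == 0L),
            class = "elastic_result")
}

#' @export
print.elastic_result <- function(x, ...) {
  verdict <- if (x$abstained) "ABSTAIN (manual review)" else
    sprintf("grade %d", x$grade)
  cat(sprintf("<elastic_result> %s @ beta=%g bits: %s (%d/%d members selected)\n",
              x$image_id, x$beta, verdict, x$n_selected, nrow(x$predictions)))
  invisible(x)
}

#' Grade many images from a cached prediction table
#'
#' Applies the entropy gate and aggregation to an already-computed
#' per-member prediction table (members are *not* re-run), which is what
#' makes beta sweeps cheap. One output row per image.
#'
#' @param predictions A [predict_members()]-shaped tibble covering one or
#'   more images (`image_id`, `member_id`, `probs`, `entropy_bits`).
#' @param beta Entropy threshold in bits.
#' @param vote Aggregation rule, see [aggregate_members()].
#' @return A tibble with one row per image: `image_id`, `grade` (`NA` =
#'   abstained), `abstained`, `n_selected`, `selected` (list-column),
#'   `aggregated` (list-column), `min_entropy`, `mean_entropy`.
#' @export
grade_from_predictions <- function(predictions, beta, vote = "soft") {
  stopifnot(nrow(predictions) > 0L)
  predictions |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_map(function(g, key) {
      sel <- select_members(g, beta)
      agg <- if (length(sel)) aggregate_members(g, sel, vote) else NULL
      tibble(image_id = key$image_id,
             grade = if (length(sel)) as.integer(which.max(agg)) else NA_integer_,
             abstained = length(sel) == 0L,
             n_selected = length(sel),
             selected = list(sel),
             aggregated = list(agg),
             min_entropy = min(g$entropy_bits),
             mean_entropy = mean(g$entropy_bits))
    }) |>
    dplyr::bind_rows()
}
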