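# Run configuration and the end-to-end grading pipeline.

run_config_defaults <- function() {
  list(
    seed = 1L,
    beta = 0.6,
    betas = NULL,              # sweep grid; NULL = default_beta_grid()
    n_classes = 3L,
    vote = "soft",
    failure_policy = "skip",
    log_level = "info",
    manifest = NULL,
    members = NULL,
    out = NULL,
    patch = list(width = 56L, height = 56L, stride_grid = 56L,
                 stride_train = 28L),
    resize = list(width = NULL, height = NULL),
    augment = list(jitter_delta = 0, seed = 1L),
    folds = list(k = 5L)
  )
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML key/value file, rejects unknown keys, and fills defaults.
#' All randomness in a run flows from the single top-level `seed`.
#'
#' @param path Path to a YAML config file, or a named list of overrides.
#' @return A validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop_parameter("config file not found: %s", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    stop_parameter("`path` must be a file path or a named list")
  }
  defaults <- run_config_defaults()
  merge_keys <- function(def, usr, prefix = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown) > 0L) {
      stop_parameter("unknown config key(s): %s",
                     paste0(prefix, unknown, collapse = ", "))
    }
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        def[[nm]] <- merge_keys(def[[nm]], usr[[nm]], paste0(prefix, nm, "."))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  cfg <- merge_keys(defaults, user %||% list())
  if (!is.numeric(cfg$beta) || cfg$beta <= 0) {
    stop_parameter("`beta` must be a positive number of bits")
  }
  structure(cfg, class = "run_config")
}

log_line <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

format_probs <- function(p) paste(formatC(p, format = "g", digits = 8), collapse = ";")

#' Run the full elastic grading pipeline
#'
#' Executes, per manifest image: read, optional bilinear resize, tile into
#' the patch grid, feature extraction, per-member prediction, entropy
#' gating at `beta`, aggregation or abstention. Then evaluates under
#' stratified cross-validation and writes all artifacts to `out`:
#' \describe{
#'   \item{predictions.csv}{per image: `image_id`, `true_grade`,
#'     `predicted_grade` (`ABSTAIN` when no member passed), `n_selected`,
#'     `selected_member_ids` (semicolon-joined), aggregated probabilities,
#'     `min_entropy`, `mean_entropy`.}
#'   \item{referrals.csv}{the abstained images, flagged for manual expert
#'     review.}
#'   \item{member_predictions.csv}{the cached per-member distributions
#'     (reused by [run_sweep()]).}
#'   \item{metrics.csv, report.json}{per-class metrics, WAA, AP.}
#'   \item{config.yaml}{the resolved configuration.}
#' }
#'
#' @param config A [load_run_config()] result, a path to a YAML file, or a
#'   named list of overrides.
#' @param members Optional list of `member_model`s; defaults to reading the
#'   registry at `config$members`.
#' @return Invisibly, a list with `graded`, `member_predictions`, `eval`,
#'   `manifest` and the output paths.
#' @export
run_pipeline <- function(config, members = NULL) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  if (is.null(cfg$manifest) || !file.exists(cfg$manifest)) {
    stop_parameter("manifest CSV not found: %s", cfg$manifest %||% "<missing>")
  }
  if (is.null(cfg$out)) stop_parameter("`out` directory must be set")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- as_tibble(read.csv(cfg$manifest, stringsAsFactors = FALSE))
  if (!all(c("image_id", "path", "grade") %in% names(manifest))) {
    stop_parameter("manifest needs columns image_id, path, grade")
  }
  if (is.null(members)) members <- read_member_registry(cfg$members)
  log_line(cfg, "info", "grading %d images with %d members at beta=%g bits",
           nrow(manifest), length(members), cfg$beta)

  preds <- purrr::pmap(manifest, function(image_id, path, grade, ...) {
    img <- read_image(if (file.exists(path)) path else
                        file.path(dirname(cfg$manifest), path))
    if (!is.null(cfg$resize$width) && !is.null(cfg$resize$height)) {
      img <- resize_image(img, cfg$resize$width, cfg$resize$height)
    }
    d <- dim(img)
    spec <- grid_spec(d[2], d[1], cfg$patch$width, cfg$patch$height,
                      cfg$patch$stride_grid)
    fg <- feature_grid(tile(img, spec), image_id = image_id,
                       true_grade = as.integer(grade))
    p <- predict_members(members, fg, cfg$failure_policy)
    for (i in seq_len(nrow(p))) {
      log_line(cfg, "debug", "image=%s member=%s entropy=%.4f decision=%s",
               image_id, p$member_id[i], p$entropy_bits[i],
               ifelse(p$entropy_bits[i] < cfg$beta, "select", "reject"))
    }
    p
  }) |> dplyr::bind_rows()

  graded <- grade_from_predictions(preds, cfg$beta, cfg$vote)
  out_tbl <- dplyr::inner_join(graded,
                               dplyr::select(manifest, "image_id",
                                             true_grade = "grade"),
                               by = "image_id") |>
    dplyr::mutate(
      predicted_grade = ifelse(.data$abstained, "ABSTAIN",
                               as.character(.data$grade)),
      selected_member_ids = purrr::map_chr(.data$selected, paste, collapse = ";"),
      aggregated_probs = purrr::map_chr(.data$aggregated, function(a) {
        if (is.null(a)) "" else format_probs(a)
      })) |>
    dplyr::select("image_id", "true_grade", "predicted_grade", "n_selected",
                  "selected_member_ids", "aggregated_probs",
                  "min_entropy", "mean_entropy")
  write.csv(out_tbl, file.path(cfg$out, "predictions.csv"), row.names = FALSE)
  referrals <- dplyr::filter(out_tbl, .data$predicted_grade == "ABSTAIN")
  write.csv(referrals, file.path(cfg$out, "referrals.csv"), row.names = FALSE)
  cache_tbl <- dplyr::mutate(preds,
                             probs = purrr::map_chr(.data$probs, format_probs))
  write.csv(cache_tbl, file.path(cfg$out, "member_predictions.csv"),
            row.names = FALSE)

  folded <- crossval_split(dplyr::select(manifest, "image_id", "grade"),
                           k = cfg$folds$k, seed = cfg$seed)
  ev <- evaluate_folds(graded, folded, cfg$n_classes, beta = cfg$beta)
  if (!is.null(ev$metrics)) {
    write.csv(dplyr::select(ev$metrics, "grade", "precision", "recall",
                            "f1", "accuracy"),
              file.path(cfg$out, "metrics.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(beta = cfg$beta, waa = ev$waa, ap = ev$ap, accuracy = ev$accuracy,
         dataset_size = ev$dataset_size,
         n_included = sum(ev$folds$n_included),
         n_excluded = sum(ev$folds$n_excluded),
         n_referred = nrow(referrals)),
    file.path(cfg$out, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  yaml::write_yaml(unclass(cfg), file.path(cfg$out, "config.yaml"))
  log_line(cfg, "info", "WAA=%.4f AP=%.2f%% (%d referred)",
           ev$waa, ev$ap, nrow(referrals))
  invisible(list(graded = graded, member_predictions = preds, eval = ev,
                 manifest = folded, out = cfg$out))
}

#' Sweep beta over a pipeline's cached member predictions
#'
#' Re-gates cached per-member predictions (from [run_pipeline()] or
#' [read_member_predictions()]) over a threshold grid, and writes
#' `sweep.csv` (`beta`, `waa`, `ap`, `n_included`, `n_excluded`) plus a
#' JSON mirror.
#'
#' @param predictions Cached prediction table.
#' @param manifest Tibble with `image_id`, `grade`, `fold`.
#' @param out Output directory.
#' @param betas Threshold grid; default [default_beta_grid()].
#' @param n_classes Number of classes.
#' @return Invisibly, the [beta_sweep()] tibble.
#' @export
run_sweep <- function(predictions, manifest, out, betas = NULL,
                      n_classes = 3L) {
  betas <- betas %||% default_beta_grid()
  sw <- beta_sweep(predictions, betas, manifest, n_classes)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(sw, file.path(out, "sweep.csv"), row.names = FALSE)
  jsonlite::write_json(sw, file.path(out, "sweep.json"), digits = NA,
                       dataframe = "rows")
  invisible(sw)
}

#' Read a cached member-prediction table back from CSV
#'
#' Inverse of the `member_predictions.csv` artifact written by
#' [run_pipeline()] (probabilities are stored semicolon-joined).
#'
#' @param path Path to `member_predictions.csv`.
#' @return A [predict_members()]-shaped tibble.
#' @export
read_member_predictions <- function(path) {
  if (!file.exists(path)) stop_parameter("prediction cache not found: %s", path)
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  raw$probs <- purrr::map(strsplit(raw$probs, ";", fixed = TRUE), as.numeric)
  raw
}
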