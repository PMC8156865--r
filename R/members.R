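#' Construct an ensemble member
#'
#' A member is a classifier bound to one context shape: given the contextual
#' feature map of a placement of that shape (and light metadata about the
#' source image), it emits a softmax-normalized class-probability vector.
#' Members are the unit the elastic gate selects between.
#'
#' @param member_id Unique identifier.
#' @param height,width Context shape in grid cells.
#' @param predict Function `(feature_map, info) -> probability vector`,
#'   where `info` is a list with `image_id`, `image_seed`, `true_grade`
#'   (metadata; honest backends must ignore `true_grade`).
#' @param n_classes Number of grade classes `c` (>= 2).
#' @param backend Backend name (`"custom"`, `"mock"`, `"multinom"`, ...).
#' @param params Backend parameter list, serialized to the member registry.
#' @param fit Optional function `(feature_maps, labels, member) -> member`
#'   returning a trained copy.
#' @return An object of class `member_model`.
#' @export
member_model <- function(member_id, height, width, predict,
                         n_classes = 3L, backend = "custom",
                         params = list(), fit = NULL) {
  if (!is_count(height) || !is_count(width)) {
    stop_geometry("member shape must be positive integers")
  }
  if (!is_count(n_classes, min = 2L)) {
    stop_parameter("`n_classes` must be an integer >= 2")
  }
  structure(list(member_id = as.character(member_id),
                 height = as.integer(height), width = as.integer(width),
                 n_classes = as.integer(n_classes),
                 backend = backend, params = params,
                 predict = predict, fit = fit),
            class = "member_model")
}

#' @export
print.member_model <- function(x, ...) {
  cat(sprintf("<member_model> %s: shape %d x %d (level %d), backend %s, %d classes\n",
              x$member_id, x$height, x$width, x$height * x$width,
              x$backend, x$n_classes))
  invisible(x)
}

#' Predict image-level class probabilities with one member
#'
#' Applies the member's classifier to every placement of its context shape in
#' the feature grid and returns the arithmetic mean of the per-placement
#' probability vectors, renormalized to sum to one. Averaging over all
#' placements lets every member see the whole image and keeps the output
#' deterministic; a full-grid member has a single placement and returns its
#' output unchanged. Each per-placement output is checked against the
#' probability-vector contract (non-negative, sums to 1 within 1e-6) and a
#' violation is reported with the member id.
#'
#' @param member A [member_model()].
#' @param grid A [feature_grid()].
#' @return A numeric probability vector of length `n_classes`.
#' @export
member_predict <- function(member, grid) {
  stopifnot(inherits(member, "member_model"), inherits(grid, "feature_grid"))
  pl <- placements(member$height, member$width,
                   attr(grid, "n_rows"), attr(grid, "n_cols"))
  info <- list(image_id = attr(grid, "image_id"),
               image_seed = id_seed(attr(grid, "image_id")),
               true_grade = attr(grid, "true_grade"))
  probs <- purrr::map2(pl$row, pl$col, function(r, cc) {
    fmap <- concat_features(grid, member$height, member$width, r, cc)
    p <- member$predict(fmap, info)
    tryCatch(check_prob_vector(p),
             elasticgrade_contract_error = function(e) {
               stop_contract("member '%s': %s", member$member_id,
                             conditionMessage(e))
             })
    if (length(p) != member$n_classes) {
      stop_contract("member '%s' emitted %d classes, expected %d",
                    member$member_id, length(p), member$n_classes)
    }
    p
  })
  avg <- Reduce(`+`, probs) / length(probs)
  avg / sum(avg)
}

#' Default member set: one member per context shape
#'
#' Builds the package's default ensemble for a grid: one member for every
#' rectangular context shape from [enumerate_shapes()], all sharing one
#' backend constructor. An explicit member list (e.g. a hand-picked
#' 17-member setup) can always be passed instead wherever a member list is
#' accepted.
#'
#' @param n_rows,n_cols Feature-grid dimensions.
#' @param min_level Smallest contextual level to include.
#' @param builder Function `(member_id, height, width) -> member_model`.
#' @return A list of `member_model` objects.
#' @export
default_members <- function(n_rows, n_cols, min_level = 1L,
                            builder = NULL) {
  shapes <- enumerate_shapes(n_rows, n_cols, min_level)
  builder <- builder %||% function(id, h, w) {
    member_model(id, h, w, predict = function(fmap, info) {
      stop_contract("member '%s' has no trained backend", id)
    })
  }
  purrr::pmap(shapes, function(height, width, level) {
    builder(sprintf("m%dx%d", height, width), height, width)
  })
}

#' Fit a member's trainable backend
#'
#' For members with backend `"multinom"`, fits a multinomial logistic
#' regression (via `nnet::multinom`) on the flattened contextual feature
#' maps of every placement of the member's shape in each training grid,
#' minimizing the categorical cross-entropy against the image-level labels.
#'
#' @param member A `member_model` with backend `"multinom"`.
#' @param grids List of [feature_grid()] objects (training images).
#' @param labels Integer grades (1..n_classes), one per grid.
#' @return A trained copy of `member` whose `predict` uses the fitted model.
#' @export
fit_member <- function(member, grids, labels) {
  if (!requireNamespace("nnet", quietly = TRUE)) {
    stop_parameter("backend 'multinom' requires the 'nnet' package")
  }
  if (member$backend != "multinom") {
    stop_parameter("fit_member supports backend 'multinom' (member '%s' has '%s')",
                   member$member_id, member$backend)
  }
  stopifnot(length(grids) == length(labels))
  rows <- list(); ys <- integer(0)
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    pl <- placements(member$height, member$width,
                     attr(g, "n_rows"), attr(g, "n_cols"))
    for (j in seq_len(nrow(pl))) {
      fmap <- concat_features(g, member$height, member$width,
                              pl$row[j], pl$col[j])
      rows[[length(rows) + 1L]] <- as.vector(fmap)
      ys <- c(ys, labels[i])
    }
  }
  X <- do.call(rbind, rows)
  y <- factor(ys, levels = seq_len(member$n_classes))
  df <- data.frame(y = y, X)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE,
                        MaxNWts = 5000, maxit = 200)
  n_classes <- member$n_classes
  member$predict <- function(fmap, info) {
    nd <- as.data.frame(t(as.vector(fmap)))
    names(nd) <- colnames(df)[-1]
    p <- predict(fit, newdata = nd, type = "probs")
    p <- as.numeric(p)
    if (length(p) == 1L) p <- c(p, 1 - p)  # 2-class multinom returns P(class 2)
    if (length(p) != n_classes) p <- rep(1 / n_classes, n_classes)
    pmax(p, 0) / sum(pmax(p, 0))
  }
  member$params$trained <- TRUE
  member
}

#' Write a member registry to disk
#'
#' One sub-directory per member containing `member.json` with the member id,
#' context shape, backend name and backend parameters. Only declarative
#' backends (e.g. `"mock"`) round-trip through the registry; in-session
#' trained state is not serialized.
#'
#' @param members List of `member_model` objects.
#' @param dir Registry directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_member_registry <- function(members, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in members) {
    mdir <- file.path(dir, m$member_id)
    dir.create(mdir, showWarnings = FALSE)
    jsonlite::write_json(
      list(member_id = m$member_id, height = m$height, width = m$width,
           n_classes = m$n_classes, backend = m$backend, params = m$params),
      file.path(mdir, "member.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a member registry from disk
#'
#' @param dir Registry directory written by [write_member_registry()].
#' @return A list of `member_model` objects. Mock members are rebuilt with
#'   their calibrated predictors; other backends come back untrained.
#' @export
read_member_registry <- function(dir) {
  if (!dir.exists(dir)) stop_parameter("member registry not found: %s", dir)
  files <- sort(list.files(dir, pattern = "^member\\.json$",
                           recursive = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop_parameter("no member.json files under %s", dir)
  purrr::map(files, function(f) {
    meta <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (identical(meta$backend, "mock")) {
      mock_member(meta$member_id, meta$height, meta$width,
                  target_accuracy = meta$params$target_accuracy,
                  concentration = meta$params$concentration,
                  seed = meta$params$seed, n_classes = meta$n_classes,
                  noise_sd = meta$params$noise_sd %||% 0.25,
                  miss_factor = meta$params$miss_factor %||% 0.4)
    } else {
      member_model(meta$member_id, meta$height, meta$width,
                   predict = function(fmap, info) {
                     stop_contract("member '%s' (backend %s) has no state on disk",
                                   meta$member_id, meta$backend)
                   },
                   n_classes = meta$n_classes, backend = meta$backend,
                   params = as.list(meta$params))
    }
  })
}
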