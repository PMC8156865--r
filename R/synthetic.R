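#' Configuration for the synthetic H&E-like image generator
#'
#' The generator emulates the statistical structure grading pipelines rely
#' on — class-conditional nuclear texture — without any visual realism: a
#' noisy eosin-pink background scattered with hematoxylin-purple elliptical
#' blobs ("nuclei") whose density and size distribution differ by grade.
#' Densities are given per patch-area so they transfer across image scales,
#' and must be strictly increasing across grades so the classes are
#' statistically separable (higher grade = more, more pleomorphic nuclei).
#'
#' The default desk-scale geometry is a 224 x 168 image with 56 x 56
#' patches at stride 56 — the same 3 x 4 grid layout as a 896 x 672 section
#' tiled into 224 x 224 patches, at 1/16 the area.
#'
#' @param image_width,image_height Image size in pixels.
#' @param patch_width,patch_height,stride Patch geometry (defines the grid
#'   and the patch-area unit for densities).
#' @param n_grades Number of grade classes (default 3).
#' @param n_per_grade Images per grade in a generated dataset.
#' @param blob_density_by_grade Mean nuclei count per patch-area, one value
#'   per grade, strictly increasing.
#' @param blob_radius_range_by_grade List of `c(min, max)` radii in pixels,
#'   one per grade (wider ranges emulate pleomorphism).
#' @param background_color,blob_color RGB means in `[0, 1]`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed Base seed for dataset generation.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_width = 224L, image_height = 168L,
                             patch_width = 56L, patch_height = 56L,
                             stride = 56L,
                             n_grades = 3L, n_per_grade = 10L,
                             blob_density_by_grade = c(4, 9, 16),
                             blob_radius_range_by_grade = list(c(3, 5), c(3, 6), c(2, 7)),
                             background_color = c(0.91, 0.73, 0.83),
                             blob_color = c(0.42, 0.26, 0.56),
                             noise_sd = 0.03, seed = 1L) {
  if (!is_count(n_grades, min = 2L)) stop_parameter("`n_grades` must be >= 2")
  if (length(blob_density_by_grade) != n_grades ||
      length(blob_radius_range_by_grade) != n_grades) {
    stop_parameter("per-grade parameter vectors must have length n_grades = %d",
                   n_grades)
  }
  if (any(diff(blob_density_by_grade) <= 0)) {
    stop_parameter("`blob_density_by_grade` must be strictly increasing across grades")
  }
  spec <- grid_spec(image_width, image_height, patch_width, patch_height, stride)
  max_r <- max(purrr::map_dbl(blob_radius_range_by_grade, max))
  if (2 * max_r >= min(image_width, image_height)) {
    stop_parameter("largest blob (radius %g) does not fit the %d x %d image",
                   max_r, image_width, image_height)
  }
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 patch_width = as.integer(patch_width),
                 patch_height = as.integer(patch_height),
                 stride = as.integer(stride),
                 grid = spec,
                 n_grades = as.integer(n_grades),
                 n_per_grade = as.integer(n_per_grade),
                 blob_density_by_grade = blob_density_by_grade,
                 blob_radius_range_by_grade = blob_radius_range_by_grade,
                 background_color = background_color,
                 blob_color = blob_color,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic graded image
#'
#' Draws a Poisson number of elliptical blobs — mean `density * A`, where
#' `A` is the image area in patch-area units — on a noisy background, with
#' radii uniform in the grade's range, random orientation and mild
#' per-blob color variation. Pixel-identical for identical `(grade, seed)`.
#'
#' @param grade Integer grade in 1..n_grades.
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this image.
#' @return A list with `image` (`H x W x 3` array in `[0, 1]`), `grade` and
#'   `n_blobs`.
#' @export
generate_image <- function(grade, config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is_count(grade) || grade > config$n_grades) {
    stop_parameter("`grade` must be an integer in 1..%d", config$n_grades)
  }
  W <- config$image_width; H <- config$image_height
  area_units <- (W * H) / (config$patch_width * config$patch_height)
  lambda <- config$blob_density_by_grade[grade] * area_units
  rr <- config$blob_radius_range_by_grade[[grade]]
  with_seed(seed, {
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      img[, , ch] <- config$background_color[ch] + rnorm(H * W, 0, config$noise_sd)
    }
    n_blobs <- rpois(1L, lambda)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 1, W); cy <- runif(1, 1, H)
      rx <- runif(1, rr[1], rr[2]); ry <- runif(1, rr[1], rr[2])
      th <- runif(1, 0, pi)
      col_b <- clamp01(config$blob_color + rnorm(3, 0, 0.04))
      # bounding box keeps the ellipse fill O(blob area), not O(image area)
      r_max <- ceiling(max(rx, ry))
      x0 <- max(1L, floor(cx - r_max)); x1 <- min(W, ceiling(cx + r_max))
      y0 <- max(1L, floor(cy - r_max)); y1 <- min(H, ceiling(cy + r_max))
      dx <- xs[y0:y1, x0:x1] - cx
      dy <- ys[y0:y1, x0:x1] - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      mask <- (u / rx)^2 + (v / ry)^2 <= 1
      for (ch in 1:3) {
        sub <- img[y0:y1, x0:x1, ch]
        sub[mask] <- col_b[ch]
        img[y0:y1, x0:x1, ch] <- sub
      }
    }
    list(image = clamp01(img), grade = as.integer(grade), n_blobs = n_blobs)
  })
}

#' Construct a calibrated mock ensemble member
#'
#' A mock member stands in for a trained image-wise classifier so the
#' elastic machinery can be exercised and calibrated without any training.
#' Its output distribution has two knobs: `target_accuracy`, the
#' probability that the distribution's mode is the true grade (wrong modes
#' are uniform over the other classes), and `concentration`, which controls
#' sharpness and hence entropy. The draw is logistic-normal: softmax of
#' `concentration * (onehot(mode) + noise)` with Gaussian logit noise, the
#' largest entry then swapped into the mode position so the mode is exact.
#' As `concentration` grows the output approaches one-hot (entropy 0); as
#' it vanishes the logits vanish too, so the output approaches the uniform
#' vector (entropy `log2(c)`). Deterministic given `(seed, image_seed)`.
#'
#' Confidence is informative: when the drawn mode is *wrong*, the effective
#' concentration is scaled down by `miss_factor`, so errors come with
#' flatter, higher-entropy outputs — the calibration property of real
#' classifiers that entropy gating relies on. Setting `miss_factor = 1`
#' decouples entropy from correctness entirely (useful as a null
#' instrument).
#'
#' Mock members read the true grade from the feature grid's metadata — they
#' are test instruments, not classifiers.
#'
#' @param member_id Identifier.
#' @param height,width Context shape in cells.
#' @param target_accuracy Mode-accuracy in `(1/c, 1]`.
#' @param concentration Positive sharpness knob.
#' @param seed Member seed.
#' @param n_classes Number of classes.
#' @param noise_sd Relative logit noise standard deviation.
#' @param miss_factor Concentration multiplier in `(0, 1]` applied when the
#'   drawn mode is wrong.
#' @return A `member_model` with backend `"mock"`.
#' @export
mock_member <- function(member_id, height = 1L, width = 1L,
                        target_accuracy = 0.9, concentration = 5,
                        seed = 1L, n_classes = 3L, noise_sd = 0.25,
                        miss_factor = 0.4) {
  if (target_accuracy <= 1 / n_classes || target_accuracy > 1) {
    stop_parameter("`target_accuracy` must be in (1/%d, 1]", n_classes)
  }
  if (concentration <= 0) stop_parameter("`concentration` must be positive")
  if (miss_factor <= 0 || miss_factor > 1) {
    stop_parameter("`miss_factor` must be in (0, 1]")
  }
  params <- list(target_accuracy = target_accuracy,
                 concentration = concentration,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 miss_factor = miss_factor)
  m <- member_model(member_id, height, width,
                    predict = NULL, n_classes = n_classes,
                    backend = "mock", params = params)
  m$predict <- function(fmap, info) {
    if (is.null(info$true_grade) || is.na(info$true_grade)) {
      stop_contract("mock member '%s' needs `true_grade` metadata on the feature grid",
                    member_id)
    }
    mock_predict(m, info$true_grade, info$image_seed)
  }
  m
}

#' Sample a mock member's output distribution for one image
#'
#' See [mock_member()] for the sampling scheme. The same `(member, image)`
#' pair always yields the same vector, so cached prediction tables and
#' re-runs agree.
#'
#' @param member A [mock_member()].
#' @param true_grade Integer true grade in 1..n_classes.
#' @param image_seed Integer seed identifying the image.
#' @return A probability vector of length `n_classes`.
#' @export
mock_predict <- function(member, true_grade, image_seed) {
  stopifnot(inherits(member, "member_model"), member$backend == "mock")
  c_n <- member$n_classes
  if (!is_count(true_grade) || true_grade > c_n) {
    stop_parameter("`true_grade` must be in 1..%d", c_n)
  }
  p <- member$params
  with_seed(combine_seeds(p$seed, image_seed), {
    mode <- if (runif(1) < p$target_accuracy) true_grade else {
      sample(setdiff(seq_len(c_n), true_grade), 1L)
    }
    conc <- p$concentration *
      if (mode == true_grade) 1 else (p$miss_factor %||% 1)
    z <- conc * ((seq_len(c_n) == mode) + rnorm(c_n, 0, p$noise_sd))
    v <- softmax(z)
    i_max <- which.max(v)
    if (i_max != mode) {  # force the mode without changing the entropy
      tmp <- v[mode]; v[mode] <- v[i_max]; v[i_max] <- tmp
    }
    v
  })
}

#' Generate a labeled synthetic dataset in memory
#'
#' `n_per_grade` images for each grade, with per-image seeds derived
#' deterministically from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `image_id`, `grade`, `image_seed`,
#'   `image` (list-column of arrays), `n_blobs`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- tidyr::expand_grid(grade = seq_len(config$n_grades),
                             rep = seq_len(config$n_per_grade))
  purrr::pmap(grid, function(grade, rep) {
    sd_i <- combine_seeds(config$seed, grade * 10000L + rep)
    g <- generate_image(grade, config, seed = sd_i)
    tibble(image_id = sprintf("g%d_%03d", grade, rep),
           grade = g$grade, image_seed = sd_i,
           image = list(g$image), n_blobs = g$n_blobs)
  }) |> dplyr::bind_rows()
}

#' Materialize a runnable demo fixture on disk
#'
#' Writes a complete, self-contained fixture: synthetic images as PNG
#' files, a `manifest.csv` (`image_id`, `path`, `grade`), and a `members/`
#' registry mixing reliable mock members (high accuracy, high
#' concentration, hence low entropy) with unreliable ones (low accuracy,
#' low concentration, high entropy). This is the fixture on which entropy
#' gating demonstrably pays: at intermediate thresholds the gate keeps the
#' reliable members and abstains on hopeless images.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param n_reliable,n_unreliable Member counts of each kind.
#' @param reliable,unreliable Lists with `target_accuracy` and
#'   `concentration` for each kind.
#' @return Invisibly, a list with `manifest` (tibble), `members` (list) and
#'   the paths written.
#' @export
build_demo_ensemble <- function(config = synthetic_config(), dir,
                                n_reliable = 4L, n_unreliable = 4L,
                                reliable = list(target_accuracy = 0.92, concentration = 5),
                                unreliable = list(target_accuracy = 0.45, concentration = 1.2)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  ds <- generate_dataset(config)
  paths <- purrr::map2_chr(ds$image_id, ds$image, function(id, img) {
    p <- file.path(img_dir, paste0(id, ".png"))
    png::writePNG(img, p)
    p
  })
  manifest <- tibble(image_id = ds$image_id, path = paths, grade = ds$grade)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  members <- demo_members(config, n_reliable, n_unreliable, reliable, unreliable)
  write_member_registry(members, file.path(dir, "members"))
  invisible(list(manifest = manifest, members = members, dir = dir,
                 images_dir = img_dir, registry_dir = file.path(dir, "members")))
}

#' Build the mixed reliable/unreliable mock member set
#'
#' Context shapes cycle through [enumerate_shapes()] for the config's grid;
#' member seeds are derived from the config seed so the ensemble is fully
#' reproducible.
#'
#' @inheritParams build_demo_ensemble
#' @return A list of mock `member_model`s.
#' @export
demo_members <- function(config, n_reliable = 4L, n_unreliable = 4L,
                         reliable = list(target_accuracy = 0.92, concentration = 5),
                         unreliable = list(target_accuracy = 0.45, concentration = 1.2)) {
  cp <- count_patches(config$grid)
  shapes <- enumerate_shapes(cp$n_rows, cp$n_cols)
  n_total <- n_reliable + n_unreliable
  idx <- rep_len(seq_len(nrow(shapes)), n_total)
  purrr::map(seq_len(n_total), function(i) {
    s <- shapes[idx[i], ]
    kind <- if (i <= n_reliable) reliable else unreliable
    tag <- if (i <= n_reliable) "rel" else "unr"
    mock_member(sprintf("%s%02d_%dx%d", tag, i, s$height, s$width),
                s$height, s$width,
                target_accuracy = kind$target_accuracy,
                concentration = kind$concentration,
                seed = combine_seeds(config$seed, 777L + i),
                n_classes = config$n_grades)
  })
}
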