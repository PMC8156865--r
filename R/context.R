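#' Enumerate the rectangular context shapes a grid supports
#'
#' Each ensemble member consumes a rectangular window of neighboring patch
#' feature maps; the window's `height x width` in grid cells is its *context
#' shape* and `height * width` its *contextual level* (1 = a single feature
#' map, `n_rows * n_cols` = the whole image). This enumerates every distinct
#' axis-aligned rectangular shape that fits the grid, one entry per shape,
#' sorted by (level, height). A 2 x 3 grid yields 6 shapes, the default
#' one-member-per-shape ensemble size for that geometry; a 3 x 4 grid
#' yields 12.
#'
#' @param n_rows,n_cols Feature-grid dimensions in cells.
#' @param min_level Smallest contextual level to keep (e.g. `2` drops the
#'   single-cell members).
#' @return A tibble with columns `height`, `width`, `level`.
#' @examples
#' enumerate_shapes(2, 3)
#' @export
enumerate_shapes <- function(n_rows, n_cols, min_level = 1L) {
  if (!is_count(n_rows) || !is_count(n_cols)) {
    stop_geometry("`n_rows` and `n_cols` must be positive integers")
  }
  if (!is_count(min_level) || min_level > n_rows * n_cols) {
    stop_parameter("`min_level` must be an integer in [1, %d]", n_rows * n_cols)
  }
  shapes <- tidyr::expand_grid(height = seq_len(n_rows), width = seq_len(n_cols))
  shapes$level <- shapes$height * shapes$width
  shapes <- shapes[shapes$level >= min_level, , drop = FALSE]
  dplyr::arrange(shapes, .data$level, .data$height)
}

#' All placements of a context shape inside a grid
#'
#' Every position where a `height x width` window of cells fits in an
#' `n_rows x n_cols` grid, row-major with 0-based top-left cell indices.
#'
#' @param height,width Context-shape dimensions in cells.
#' @param n_rows,n_cols Grid dimensions in cells.
#' @return A tibble with columns `row`, `col`.
#' @export
placements <- function(height, width, n_rows, n_cols) {
  if (!is_count(height) || !is_count(width)) {
    stop_geometry("shape dimensions must be positive integers")
  }
  if (height > n_rows || width > n_cols) {
    stop_geometry("shape %d x %d does not fit in a %d x %d grid",
                  height, width, n_rows, n_cols)
  }
  tidyr::expand_grid(row = seq_len(n_rows - height + 1L) - 1L,
                     col = seq_len(n_cols - width + 1L) - 1L)
}

#' Build a feature grid from a patch grid
#'
#' Applies a patch-level feature extractor to every cell of a patch grid.
#' The extractor is pluggable: any function mapping an `h x w x 3` patch to
#' a numeric array of fixed shape. The default, [texture_extractor()], is a
#' deterministic hand-crafted descriptor so the whole pipeline runs without
#' trained weights; a fine-tuned CNN backbone can be dropped in through the
#' same interface.
#'
#' @param patches A [tile()] result with pixels.
#' @param extractor Function patch -> feature array (uniform shape).
#' @param image_id Identifier of the source image.
#' @param true_grade Optional known grade, carried as metadata (used by mock
#'   members and training backends; never by the elastic gate).
#' @return A `feature_grid`: a tibble with columns `row`, `col` and a
#'   `feature` list-column, plus attributes `n_rows`, `n_cols`, `cell_dim`,
#'   `image_id`, `true_grade`.
#' @export
feature_grid <- function(patches, extractor = texture_extractor(),
                         image_id = "image", true_grade = NA_integer_) {
  stopifnot(inherits(patches, "patch_grid"))
  if (is.null(patches$pixels)) {
    stop_contract("patch grid has no `pixels` column; tile with keep_pixels = TRUE")
  }
  feats <- purrr::map(patches$pixels, extractor)
  dims <- purrr::map(feats, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    stop_contract("extractor produced feature maps of differing shapes")
  }
  out <- tibble(row = patches$row, col = patches$col, feature = feats)
  structure(out,
            n_rows = attr(patches, "n_rows"),
            n_cols = attr(patches, "n_cols"),
            cell_dim = dims[[1]],
            image_id = image_id,
            true_grade = true_grade,
            class = c("feature_grid", class(out)))
}

#' Hand-crafted texture descriptor for patches
#'
#' Returns an extractor that pools a patch into a `pool x pool` spatial grid
#' and computes, per pooling cell and per color channel, the mean intensity,
#' the standard deviation and the edge energy (mean absolute horizontal plus
#' vertical difference). The output is a `pool x pool x 9` array. Nuclei-rich
#' regions are darker, more variable and edge-dense than stroma, so these
#' statistics separate grade-like texture classes without any training.
#'
#' @param pool Pooling grid side length (cells per axis).
#' @return A function `patch -> array(pool, pool, 9)`.
#' @export
texture_extractor <- function(pool = 2L) {
  if (!is_count(pool)) stop_parameter("`pool` must be a positive integer")
  function(patch) {
    d <- dim(patch)
    ry <- floor(seq(0, d[1], length.out = pool + 1L))
    rx <- floor(seq(0, d[2], length.out = pool + 1L))
    out <- array(0, c(pool, pool, 9L))
    for (i in seq_len(pool)) {
      for (j in seq_len(pool)) {
        block <- patch[(ry[i] + 1L):ry[i + 1L], (rx[j] + 1L):rx[j + 1L], ,
                       drop = FALSE]
        for (ch in 1:3) {
          b <- block[, , ch]
          gx <- if (ncol(b) > 1) mean(abs(b[, -1] - b[, -ncol(b)])) else 0
          gy <- if (nrow(b) > 1) mean(abs(b[-1, ] - b[-nrow(b), ])) else 0
          out[i, j, ch] <- mean(b)
          out[i, j, 3L + ch] <- stats::sd(as.vector(b))
          out[i, j, 6L + ch] <- gx + gy
        }
      }
    }
    out[is.na(out)] <- 0
    out
  }
}

#' Concatenate the feature maps of a context window
#'
#' Assembles the cell feature maps of a `height x width` window into one
#' contextual feature map, preserving the spatial arrangement: cells that
#' are row-adjacent in the grid abut horizontally, column-adjacent cells
#' abut vertically. The output is
#' `(height * cell_h) x (width * cell_w) x channels`.
#'
#' @param grid A [feature_grid()].
#' @param height,width Context-shape dimensions in cells.
#' @param row,col 0-based grid position of the window's top-left cell.
#' @return The contextual feature map (numeric array).
#' @export
concat_features <- function(grid, height, width, row = 0L, col = 0L) {
  stopifnot(inherits(grid, "feature_grid"))
  n_rows <- attr(grid, "n_rows")
  n_cols <- attr(grid, "n_cols")
  if (row < 0 || col < 0 || row + height > n_rows || col + width > n_cols) {
    stop_geometry("window %dx%d at (%d,%d) exceeds the %dx%d grid",
                  height, width, row, col, n_rows, n_cols)
  }
  cd <- attr(grid, "cell_dim")
  ch <- cd[1]; cw <- cd[2]
  nchan <- if (length(cd) >= 3L) cd[3] else 1L
  out <- array(0, c(height * ch, width * cw, nchan))
  cells <- grid
  for (r in seq_len(height) - 1L) {
    for (cc in seq_len(width) - 1L) {
      f <- cells$feature[[which(cells$row == row + r & cells$col == col + cc)]]
      if (!identical(dim(f)[1:2], cd[1:2])) {
        stop_contract("heterogeneous cell shapes in feature grid")
      }
      out[(r * ch + 1L):((r + 1L) * ch), (cc * cw + 1L):((cc + 1L) * cw), ] <- f
    }
  }
  out
}
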