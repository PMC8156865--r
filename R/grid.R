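#' Define patch-grid geometry for an image
#'
#' A grid spec records the image size, the patch size and the stride used to
#' tile an image into (possibly overlapping) patches. The number of patches
#' along each axis follows the standard sliding-window count with the
#' quotients floored, so any right/bottom margin narrower than one stride
#' step is dropped and the grid is anchored at the top-left pixel:
#' \deqn{k = \left(1 + \lfloor (W - w)/s \rfloor\right)
#'           \left(1 + \lfloor (H - h)/s \rfloor\right)}
#'
#' @param image_width,image_height Image dimensions `W`, `H` in pixels.
#' @param patch_width,patch_height Patch dimensions `w`, `h` in pixels; must
#'   not exceed the image dimensions.
#' @param stride Stride `s` in pixels (>= 1). `stride == patch` size gives
#'   non-overlapping tiles; smaller strides give partially overlapping ones.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(896, 672, 224, 224, 224)   # 3 x 4 grid, 12 patches
#' @export
grid_spec <- function(image_width, image_height, patch_width, patch_height,
                      stride) {
  fields <- list(image_width = image_width, image_height = image_height,
                 patch_width = patch_width, patch_height = patch_height,
                 stride = stride)
  for (nm in names(fields)) {
    if (!is_count(fields[[nm]])) {
      stop_geometry("`%s` must be a positive integer (got %s)", nm,
                    paste(fields[[nm]], collapse = ","))
    }
  }
  if (patch_width > image_width || patch_height > image_height) {
    stop_geometry("patch (%d x %d) does not fit inside image (%d x %d)",
                  patch_width, patch_height, image_width, image_height)
  }
  structure(lapply(fields, as.integer), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cp <- count_patches(x)
  cat(sprintf("<grid_spec> image %d x %d, patch %d x %d, stride %d -> %d x %d grid (k = %d)\n",
              x$image_width, x$image_height, x$patch_width, x$patch_height,
              x$stride, cp$n_rows, cp$n_cols, cp$k))
  invisible(x)
}

#' Count the patches a grid spec produces
#'
#' Applies the floored sliding-window count (see [grid_spec()]) along each
#' axis. For the 1280 x 960 sections used in breast-carcinoma grading with
#' 224 x 224 patches at stride 224 this gives 20 patches; the 896 x 672
#' down-sampled scale gives a 3 x 4 grid of 12; 448 x 336 at stride 112
#' gives 6.
#'
#' @param spec A [grid_spec()].
#' @return A one-row tibble with columns `n_rows`, `n_cols`, `k`.
#' @examples
#' count_patches(grid_spec(1280, 960, 224, 224, 224))$k  # 20
#' @export
count_patches <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n_cols <- 1L + (spec$image_width - spec$patch_width) %/% spec$stride
  n_rows <- 1L + (spec$image_height - spec$patch_height) %/% spec$stride
  tibble(n_rows = n_rows, n_cols = n_cols, k = n_rows * n_cols)
}

#' Tile an image into a patch grid
#'
#' Cuts the image into patches at every grid origin, row-major from the
#' top-left pixel. Pixel coordinates are 0-based and patch intervals are
#' half-open, so the patch at origin `(x, y)` covers columns `[x, x + w)`
#' and rows `[y, y + h)`.
#'
#' @param image An RGB raster: numeric array `H x W x 3` with values in
#'   `[0, 1]` (the convention used by [png::readPNG()]).
#' @param spec A [grid_spec()] whose image dimensions match `image`.
#' @param keep_pixels If `FALSE`, only origins are returned (no `pixels`
#'   list-column); useful when only the geometry is needed.
#' @return A tibble of class `patch_grid` with one row per patch, columns
#'   `row`, `col` (0-based grid index), `x`, `y` (0-based pixel origin) and,
#'   unless `keep_pixels = FALSE`, a `pixels` list-column of
#'   `h x w x 3` arrays. Attributes `n_rows`, `n_cols` and `spec` carry the
#'   grid geometry.
#' @export
tile <- function(image, spec, keep_pixels = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop_geometry("`image` must be an H x W x 3 array")
  }
  if (d[1] != spec$image_height || d[2] != spec$image_width) {
    stop_geometry("image is %d x %d but spec expects %d x %d",
                  d[2], d[1], spec$image_width, spec$image_height)
  }
  cp <- count_patches(spec)
  grid <- tidyr::expand_grid(row = seq_len(cp$n_rows) - 1L,
                             col = seq_len(cp$n_cols) - 1L)
  grid$x <- grid$col * spec$stride
  grid$y <- grid$row * spec$stride
  if (keep_pixels) {
    w <- spec$patch_width
    h <- spec$patch_height
    grid$pixels <- purrr::map2(grid$x, grid$y, function(x, y) {
      image[(y + 1L):(y + h), (x + 1L):(x + w), , drop = FALSE]
    })
  }
  structure(grid,
            n_rows = cp$n_rows, n_cols = cp$n_cols, spec = spec,
            class = c("patch_grid", class(grid)))
}

#' Read an RGB image from a PNG or TIFF file
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An `H x W x 3` numeric array with values in `[0, 1]`. Grayscale
#'   images are expanded to three identical channels; any alpha channel is
#'   dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_parameter("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_parameter("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop_parameter("unsupported image format '.%s' (PNG and TIFF only)", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write the patches of a patch grid to PNG files
#'
#' Files are named `<image_id>_r<row>_c<col>.png` using the 0-based grid
#' indices.
#'
#' @param grid A [tile()] result with its `pixels` column.
#' @param dir Output directory (created if needed).
#' @param image_id Identifier used as the filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_patches <- function(grid, dir, image_id) {
  stopifnot(inherits(grid, "patch_grid"), !is.null(grid$pixels))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(list(grid$row, grid$col, grid$pixels),
    function(r, c, px) {
      p <- file.path(dir, sprintf("%s_r%d_c%d.png", image_id, r, c))
      png::writePNG(px, p)
      p
    })
  invisible(paths)
}

#' Down-sample an image by bilinear interpolation
#'
#' High-resolution sections (e.g. 1280 x 960) are typically down-sampled to a
#' working scale such as 896 x 672 before tiling.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param width,height Target dimensions in pixels.
#' @return The resized array.
#' @export
resize_image <- function(image, width, height) {
  if (!is_count(width) || !is_count(height)) {
    stop_parameter("`width` and `height` must be positive integers")
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop_parameter("resizing requires the 'EBImage' package")
  }
  out <- EBImage::resize(EBImage::Image(aperm(image, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = width, h = height)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}
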