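# Raster transforms for training-time augmentation. Patches are augmented
# with 90-degree rotation plus horizontal/vertical flips; whole images with a
# 180-degree rotation plus flips (a 90-degree turn would change the aspect
# ratio of a non-square image and break the patch grid).

rot90_cw <- function(x) {
  n <- dim(x)[1]
  if (n != dim(x)[2]) stop_geometry("90-degree rotation requires a square raster")
  y <- aperm(x, c(2, 1, 3))
  y[, n:1, , drop = FALSE]
}

rot180 <- function(x) {
  x[dim(x)[1]:1, dim(x)[2]:1, , drop = FALSE]
}

hflip <- function(x) x[, dim(x)[2]:1, , drop = FALSE]
vflip <- function(x) x[dim(x)[1]:1, , , drop = FALSE]

# Per-channel multiplicative color jitter: each channel is scaled by a factor
# drawn uniformly from [1 - delta, 1 + delta], then clamped to [0, 1].
color_jitter <- function(x, delta) {
  f <- runif(3L, 1 - delta, 1 + delta)
  for (ch in 1:3) x[, , ch] <- clamp01(x[, , ch] * f[ch])
  x
}

#' Augment a patch or image with rotations and flips
#'
#' Produces the deterministic set of dihedral variants used to augment
#' training data: patches get \{identity, 90-degree rotation, horizontal
#' flip, vertical flip\} (rotation by 90 degrees requires a square patch);
#' whole images get \{identity, 180-degree rotation, horizontal flip,
#' vertical flip\}. An optional per-channel multiplicative color jitter
#' (factors drawn uniformly from `[1 - jitter_delta, 1 + jitter_delta]`)
#' emulates stain-intensity variation; it is off by default and fully
#' reproducible given `seed`.
#'
#' @param x An `H x W x 3` raster in `[0, 1]`.
#' @param mode `"patch"` (square tiles, 90-degree rotation) or `"image"`
#'   (180-degree rotation, aspect preserved).
#' @param jitter_delta Color-jitter half-width in `[0, 1)`; `0` disables it.
#' @param seed Integer seed for the jitter draws.
#' @return A named list of rasters: `identity`, `rot90` or `rot180`,
#'   `hflip`, `vflip` (fixed order).
#' @examples
#' p <- array(runif(4 * 4 * 3), c(4, 4, 3))
#' names(augment(p, "patch"))
#' @export
augment <- function(x, mode = c("patch", "image"), jitter_delta = 0,
                    seed = 1L) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop_geometry("`x` must be an H x W x 3 array")
  }
  if (jitter_delta < 0 || jitter_delta >= 1) {
    stop_parameter("`jitter_delta` must be in [0, 1)")
  }
  variants <- if (mode == "patch") {
    if (d[1] != d[2]) {
      stop_geometry("mode = \"patch\" requires a square raster (got %d x %d)",
                    d[2], d[1])
    }
    list(identity = x, rot90 = rot90_cw(x), hflip = hflip(x), vflip = vflip(x))
  } else {
    list(identity = x, rot180 = rot180(x), hflip = hflip(x), vflip = vflip(x))
  }
  if (jitter_delta > 0) {
    variants <- with_seed(seed, lapply(variants, color_jitter, delta = jitter_delta))
  }
  variants
}
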