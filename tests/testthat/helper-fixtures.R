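# Shared fixture builders. Everything is generated in code at test time.

# Random points on the probability simplex (uniform via normalized exponentials).
random_simplex <- function(n, c_n, seed = 1L) {
  set.seed(seed)
  t(replicate(n, {
    e <- -log(runif(c_n))
    e / sum(e)
  }))
}

# A hand-built prediction table for one or more images: `entropies` is a
# named list image_id -> numeric vector; probability vectors are constructed
# with exactly the requested entropy by two-point mixtures where possible,
# otherwise supplied directly via `probs`.
prediction_table <- function(probs_by_image) {
  purrr::imap(probs_by_image, function(plist, img) {
    tibble::tibble(
      image_id = img,
      member_id = sprintf("m%02d", seq_along(plist)),
      probs = plist,
      entropy_bits = vapply(plist, shannon_entropy, numeric(1)))
  }) |> dplyr::bind_rows()
}

# Tiny synthetic config used across tests: 112 x 84 image, 28 x 28 patches,
# stride 28 -> the same 3 x 4 grid as the full-scale geometry.
tiny_config <- function(n_per_grade = 2L, seed = 1L) {
  synthetic_config(image_width = 112L, image_height = 84L,
                   patch_width = 28L, patch_height = 28L, stride = 28L,
                   n_per_grade = n_per_grade, seed = seed)
}

# Mock-member prediction table over a labeled manifest, one row per
# (image, member); labels 1..c recycled.
mock_prediction_table <- function(members, manifest) {
  purrr::pmap(manifest, function(image_id, grade, image_seed, ...) {
    tibble::tibble(
      image_id = image_id,
      member_id = purrr::map_chr(members, "member_id"),
      probs = purrr::map(members, mock_predict, true_grade = grade,
                         image_seed = image_seed),
      entropy_bits = purrr::map_dbl(probs, shannon_entropy))
  }) |> dplyr::bind_rows()
}

# Labels-only manifest (no images needed when members are mocks).
label_manifest <- function(n_per_grade, n_grades = 3L, seed = 1L) {
  tibble::tibble(
    grade = rep(seq_len(n_grades), each = n_per_grade),
    image_id = sprintf("g%d_%03d", grade, rep(seq_len(n_per_grade), n_grades)),
    image_seed = seed * 100000L + seq_len(n_grades * n_per_grade))
}

# The mixed reliable/unreliable fixture of the end-to-end demonstration:
# study conditions fixed once (see the methods vignette).
mixed_fixture_members <- function(seed, n_classes = 3L) {
  shapes <- enumerate_shapes(3, 4)
  build <- function(tag, i, acc, conc) {
    s <- shapes[((i - 1L) %% nrow(shapes)) + 1L, ]
    mock_member(sprintf("%s%02d", tag, i), s$height, s$width,
                target_accuracy = acc, concentration = conc,
                seed = seed * 1000L + i, n_classes = n_classes)
  }
  c(purrr::map(1:4, ~build("rel", .x, 0.92, 5)),
    purrr::map(5:8, ~build("unr", .x, 0.45, 1.2)))
}
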