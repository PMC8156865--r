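# Contextual groupings: shape enumeration, placements, feature concatenation,
# and the member prediction contract.

test_that("enumerate_shapes matches brute-force sub-rectangle enumeration up to 5x5", {
  for (nr in 1:5) {
    for (nc in 1:5) {
      oracle <- unique(expand.grid(height = 1:nr, width = 1:nc))
      got <- enumerate_shapes(nr, nc)
      expect_equal(nrow(got), nrow(oracle))
      expect_setequal(paste(got$height, got$width),
                      paste(oracle$height, oracle$width))
      # sorted by (level, height), one entry per shape
      expect_false(is.unsorted(got$level))
      expect_equal(anyDuplicated(got[c("height", "width")]), 0)
    }
  }
})

test_that("shape enumeration reproduces the per-grid member counts", {
  expect_equal(nrow(enumerate_shapes(2, 3)), 6)   # 2x3 grid -> 6 members
  expect_equal(nrow(enumerate_shapes(3, 4)), 12)  # 3x4 grid -> 12 shapes
  expect_equal(enumerate_shapes(1, 1),
               tibble::tibble(height = 1L, width = 1L, level = 1L))
})

test_that("min_level filters levels and is validated", {
  sh <- enumerate_shapes(3, 4, min_level = 2)
  expect_true(all(sh$level >= 2))
  expect_equal(nrow(sh), 11)
  expect_error(enumerate_shapes(3, 4, min_level = 13),
               class = "elasticgrade_parameter_error")
})

test_that("placements enumerate every fitting window, row-major", {
  expect_equal(nrow(placements(3, 4, 3, 4)), 1)
  expect_equal(nrow(placements(1, 2, 3, 4)), 9)
  expect_equal(nrow(placements(2, 2, 2, 3)), 2)
  pl <- placements(2, 2, 3, 4)
  expect_equal(nrow(pl), (3 - 2 + 1) * (4 - 2 + 1))
  expect_equal(pl$row, rep(0:1, each = 3))
  expect_error(placements(4, 1, 3, 4), class = "elasticgrade_geometry_error")
})

test_that("placements of any shape jointly cover every grid cell", {
  set.seed(3)
  for (i in 1:20) {
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    h <- sample(1:nr, 1); w <- sample(1:nc, 1)
    pl <- placements(h, w, nr, nc)
    covered <- matrix(FALSE, nr, nc)
    for (j in seq_len(nrow(pl))) {
      covered[pl$row[j] + seq_len(h), pl$col[j] + seq_len(w)] <- TRUE
    }
    expect_true(all(covered))
  }
})

make_feature_grid <- function(n_rows, n_cols, cell = c(2, 2, 1),
                              image_id = "img", true_grade = 1L) {
  img <- array(runif(n_rows * 8 * n_cols * 8 * 3), c(n_rows * 8, n_cols * 8, 3))
  pg <- tile(img, grid_spec(n_cols * 8, n_rows * 8, 8, 8, 8))
  feature_grid(pg, texture_extractor(pool = cell[1]),
               image_id = image_id, true_grade = true_grade)
}

test_that("concat_features preserves spatial arrangement and conserves elements", {
  set.seed(5)
  fg <- make_feature_grid(2, 3)
  # 1x1 window is the identity on its cell
  cellA <- fg$feature[[which(fg$row == 0 & fg$col == 0)]]
  expect_identical(concat_features(fg, 1, 1, 0, 0), cellA)
  # 1x2 window abuts horizontally; the left half is cell A exactly
  cellB <- fg$feature[[which(fg$row == 0 & fg$col == 1)]]
  ab <- concat_features(fg, 1, 2, 0, 0)
  cw <- dim(cellA)[2]
  expect_equal(ab[, 1:cw, , drop = FALSE], cellA)
  expect_equal(ab[, cw + 1:cw, , drop = FALSE], cellB)
  # column-adjacent cells abut vertically
  cellC <- fg$feature[[which(fg$row == 1 & fg$col == 0)]]
  ac <- concat_features(fg, 2, 1, 0, 0)
  chh <- dim(cellA)[1]
  expect_equal(ac[chh + 1:chh, , , drop = FALSE], cellC)
  # 2x2 window: area is 4x a cell and every element appears exactly once
  quad <- concat_features(fg, 2, 2, 0, 0)
  expect_equal(length(quad), 4 * length(cellA))
  cellD <- fg$feature[[which(fg$row == 1 & fg$col == 1)]]
  expect_equal(sum(quad), sum(cellA) + sum(cellB) + sum(cellC) + sum(cellD))
  # out-of-grid window rejected
  expect_error(concat_features(fg, 2, 3, 1, 1),
               class = "elasticgrade_geometry_error")
})

test_that("texture extractor output is deterministic with fixed shape", {
  patch <- array(runif(16 * 16 * 3), c(16, 16, 3))
  ex <- texture_extractor(pool = 2)
  f1 <- ex(patch); f2 <- ex(patch)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(2, 2, 9))
  # mean channels reproduce block means
  expect_equal(f1[1, 1, 1], mean(patch[1:8, 1:8, 1]))
})

test_that("member_predict averages placements and enforces the contract", {
  set.seed(11)
  fg <- make_feature_grid(2, 3)
  # a member returning a constant vector returns it unchanged
  const <- member_model("const", 1, 2,
                        predict = function(f, info) c(0.2, 0.3, 0.5))
  expect_equal(member_predict(const, fg), c(0.2, 0.3, 0.5))
  # full-grid member equals predict on the single full concatenation
  probe <- function(f, info) {
    s <- sum(f)
    softmax(c(s, -s, 0))
  }
  full <- member_model("full", 2, 3, predict = probe)
  expect_equal(member_predict(full, fg),
               probe(concat_features(fg, 2, 3, 0, 0), NULL))
  # two alternating one-hot placements average to their mean
  flip <- local({
    i <- 0
    function(f, info) {
      i <<- i + 1
      if (i %% 2 == 1) c(1, 0, 0) else c(0, 1, 0)
    }
  })
  two <- member_model("two", 2, 3, predict = flip)
  # 2x3 shape in 2x3 grid has one placement; use 2x2 (2 placements)
  two <- member_model("two", 2, 2, predict = flip)
  expect_equal(member_predict(two, fg), c(0.5, 0.5, 0))
  # malformed output surfaces the member id
  bad <- member_model("badmember", 1, 1,
                      predict = function(f, info) c(0.9, 0.3, 0.1))
  expect_error(member_predict(bad, fg), "badmember",
               class = "elasticgrade_contract_error")
})

test_that("multinom backend learns separable synthetic grades", {
  skip_if_not_installed("nnet")
  cfg <- tiny_config(n_per_grade = 6L, seed = 21L)
  ds <- generate_dataset(cfg)
  grids <- purrr::pmap(ds, function(image_id, grade, image_seed, image, ...) {
    feature_grid(tile(image, cfg$grid), texture_extractor(1L),
                 image_id = image_id, true_grade = grade)
  })
  m <- member_model("ml_full", 3, 4, predict = NULL, backend = "multinom")
  train <- c(1:4, 7:10, 13:16)
  test_idx <- setdiff(seq_len(nrow(ds)), train)
  fitted <- fit_member(m, grids[train], ds$grade[train])
  preds <- purrr::map_int(grids[test_idx],
                          ~which.max(member_predict(fitted, .x)))
  # separable classes: a trained full-context member clearly beats chance
  expect_gt(mean(preds == ds$grade[test_idx]), 1 / 3)
})

test_that("member registry round-trips mock members", {
  dir <- withr::local_tempdir()
  members <- list(
    mock_member("a", 1, 2, target_accuracy = 0.9, concentration = 4, seed = 5L),
    mock_member("b", 2, 2, target_accuracy = 0.5, concentration = 1, seed = 6L))
  write_member_registry(members, dir)
  back <- read_member_registry(dir)
  expect_equal(purrr::map_chr(back, "member_id"), c("a", "b"))
  expect_equal(back[[1]]$params$concentration, 4)
  # reconstructed mock produces identical draws
  expect_identical(mock_predict(back[[1]], 2, 123L),
                   mock_predict(members[[1]], 2, 123L))
})
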