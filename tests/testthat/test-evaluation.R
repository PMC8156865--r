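# Metrics, WAA/AP, cross-validation and the beta sweep.

test_that("classification metrics reproduce hand-computed contingencies", {
  m <- classification_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  c1 <- m[m$grade == "1", ]
  c2 <- m[m$grade == "2", ]
  expect_equal(c1$precision, 1)
  expect_equal(c1$recall, 0.5)
  expect_equal(c2$precision, 2 / 3)
  expect_equal(c2$recall, 1)
  expect_equal(attr(m, "accuracy"), 0.75)
  tot <- m[m$grade == "Total", ]
  expect_equal(tot$precision, mean(c(1, 2 / 3)))
  expect_equal(tot$accuracy, 0.75)
})

test_that("perfect predictions score 1 everywhere; single-class predictions degrade", {
  y <- rep(1:3, each = 4)
  m <- classification_metrics(y, y, 3)
  expect_true(all(m$precision == 1 & m$recall == 1 & m$f1 == 1))
  suppressWarnings(m1 <- classification_metrics(y, rep(2L, 12), 3))
  expect_equal(m1$recall[m1$grade == "2"], 1)
  expect_equal(m1$recall[m1$grade %in% c("1", "3")], c(0, 0))
  expect_true(any(m1$zero_division))
})

test_that("metrics match a brute-force confusion oracle on random labels", {
  set.seed(20)
  for (case in 1:25) {
    c_n <- sample(2:5, 1)
    n <- sample(10:60, 1)
    y <- sample(c_n, n, replace = TRUE)
    p <- sample(c_n, n, replace = TRUE)
    m <- suppressWarnings(classification_metrics(y, p, c_n))
    # independent oracle: per-class counts by direct logical sums
    for (k in seq_len(c_n)) {
      tp <- sum(y == k & p == k)
      fp <- sum(y != k & p == k)
      fn <- sum(y == k & p != k)
      row <- m[m$grade == as.character(k), ]
      expect_equal(row$tp, tp)
      expect_equal(row$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
      expect_equal(row$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
    }
    expect_equal(attr(m, "accuracy"), mean(y == p))
  }
})

test_that("weighted Total row weights by class support", {
  y <- c(rep(1, 9), rep(2, 1))
  p <- c(rep(1, 9), 1)
  mw <- suppressWarnings(classification_metrics(y, p, 2, average = "weighted"))
  tot <- mw[mw$grade == "Total", ]
  expect_equal(tot$recall, 0.9 * 1 + 0.1 * 0)
})

test_that("WAA reproduces its worked examples and edge cases", {
  folds <- tibble::tibble(fold = 1:2, n_included = c(10L, 10L),
                          n_excluded = c(0L, 0L), n_correct = c(10L, 5L),
                          accuracy = c(1, 0.5), undefined = FALSE)
  expect_equal(waa(folds), 0.75)
  folds2 <- tibble::tibble(fold = 1:2, n_included = c(30L, 10L),
                           n_excluded = c(0L, 0L), n_correct = c(27L, 6L),
                           accuracy = c(0.9, 0.6), undefined = FALSE)
  expect_equal(waa(folds2), 0.825)
  single <- folds[1, ]
  expect_equal(waa(single), 1)
  # folds with d_i = 0 contribute nothing
  folds3 <- dplyr::bind_rows(folds2,
                             tibble::tibble(fold = 3L, n_included = 0L,
                                            n_excluded = 5L, n_correct = 0L,
                                            accuracy = NA_real_,
                                            undefined = TRUE))
  expect_equal(waa(folds3), 0.825)
  all_empty <- tibble::tibble(fold = 1L, n_included = 0L, n_excluded = 4L,
                              n_correct = 0L, accuracy = NA_real_,
                              undefined = TRUE)
  expect_error(waa(all_empty), class = "elasticgrade_undefined_error")
})

test_that("AP reproduces its worked examples and checks consistency", {
  folds <- tibble::tibble(fold = 1:5, n_included = rep(59L, 5),
                          n_excluded = rep(1L, 5))
  expect_equal(ap(folds, 300), 5 / 300 * 100, tolerance = 1e-12)
  expect_equal(round(ap(folds, 300), 4), 1.6667)
  none <- tibble::tibble(fold = 1:2, n_included = c(10L, 10L),
                         n_excluded = c(0L, 0L))
  expect_equal(ap(none, 20), 0)
  all_out <- tibble::tibble(fold = 1L, n_included = 0L, n_excluded = 12L)
  expect_equal(ap(all_out, 12), 100)
  expect_error(ap(none, 21), class = "elasticgrade_contract_error")
})

test_that("fold outcomes count inclusion, exclusion and correctness per fold", {
  graded <- tibble::tibble(
    image_id = sprintf("i%d", 1:6),
    grade = c(1L, 2L, NA, 3L, NA, 2L),
    abstained = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    truth = c(1L, 2L, 1L, 1L, 2L, 2L),
    fold = c(1L, 1L, 1L, 2L, 2L, 2L))
  fo <- fold_outcomes(graded)
  expect_equal(fo$n_included, c(2L, 2L))
  expect_equal(fo$n_excluded, c(1L, 1L))
  expect_equal(fo$accuracy, c(1, 0.5))
  expect_equal(sum(fo$n_included + fo$n_excluded), nrow(graded))
})

test_that("crossval_split is stratified, disjoint, exhaustive, deterministic", {
  manifest <- label_manifest(20)  # 60 images, 3 grades
  f1 <- crossval_split(manifest, k = 5, seed = 9L)
  f2 <- crossval_split(manifest, k = 5, seed = 9L)
  f3 <- crossval_split(manifest, k = 5, seed = 10L)
  expect_identical(f1$fold, f2$fold)
  expect_false(identical(f1$fold, f3$fold))
  expect_equal(sort(unique(f1$fold)), 1:5)
  expect_equal(as.integer(table(f1$fold)), rep(12L, 5))
  # stratification: each fold holds 4 images of each grade
  tab <- table(f1$grade, f1$fold)
  expect_true(all(tab == 4))
  # leave-one-out corner
  loo <- crossval_split(manifest[1:6, ], k = 6, seed = 1L)
  expect_equal(sort(loo$fold), 1:6)
  # scarce class falls back to unstratified with a warning
  scarce <- manifest[c(1:10, 21, 41), ]
  expect_warning(crossval_split(scarce, k = 5, seed = 1L), "unstratified")
})

test_that("WAA equals pooled accuracy when nothing is abstained", {
  set.seed(22)
  manifest <- label_manifest(10)
  members <- mixed_fixture_members(seed = 4L)
  tbl <- mock_prediction_table(members, manifest)
  folded <- crossval_split(manifest, k = 5, seed = 2L)
  graded <- grade_from_predictions(tbl, beta = 2)  # above log2(3): full coverage
  ev <- evaluate_folds(graded, folded, beta = 2)
  expect_equal(ev$ap, 0)
  joined <- dplyr::inner_join(graded, folded, by = "image_id")
  expect_equal(ev$waa, mean(joined$grade.x == joined$grade.y))
  expect_equal(ev$waa, ev$accuracy)
})

test_that("beta sweep rows are ascending in beta with non-increasing AP", {
  manifest <- label_manifest(8)
  members <- mixed_fixture_members(seed = 6L)
  tbl <- mock_prediction_table(members, manifest)
  folded <- crossval_split(manifest, k = 4, seed = 3L)
  betas <- c(2, 1e-6, 0.3, 0.8, 1.2, 0.05)
  sw <- beta_sweep(tbl, betas, folded)
  expect_equal(sw$beta, sort(betas))
  expect_false(is.unsorted(rev(sw$ap)))
  expect_equal(sw$n_included + sw$n_excluded, rep(nrow(manifest), nrow(sw)))
  # brute-force recount of exclusions at each beta
  for (i in seq_len(nrow(sw))) {
    excl <- tbl |>
      dplyr::group_by(image_id) |>
      dplyr::summarise(out = all(entropy_bits >= sw$beta[i])) |>
      dplyr::pull(out) |> sum()
    expect_equal(sw$n_excluded[i], excl)
  }
  # full-coverage limit: beta above log2(c) has AP 0 and WAA = pooled accuracy
  expect_equal(sw$ap[nrow(sw)], 0)
  expect_error(beta_sweep(tbl, numeric(0), folded),
               class = "elasticgrade_parameter_error")
})

test_that("tidy and glance summarize an evaluation", {
  manifest <- label_manifest(5)
  members <- mixed_fixture_members(seed = 8L)
  tbl <- mock_prediction_table(members, manifest)
  folded <- crossval_split(manifest, k = 3, seed = 1L)
  ev <- evaluate_folds(grade_from_predictions(tbl, 0.6), folded, beta = 0.6)
  td <- tidy(ev)
  expect_equal(td$grade, c("1", "2", "3", "Total"))
  expect_true(all(c("precision", "recall", "f1", "accuracy") %in% names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$dataset_size, 15)
  expect_equal(gl$n_included + gl$n_excluded, 15)
  expect_equal(gl$beta, 0.6)
})

test_that("sweep and evaluation plots build", {
  manifest <- label_manifest(5)
  members <- mixed_fixture_members(seed = 12L)
  tbl <- mock_prediction_table(members, manifest)
  folded <- crossval_split(manifest, k = 3, seed = 1L)
  sw <- beta_sweep(tbl, c(0.1, 0.6, 2), folded)
  expect_s3_class(autoplot(sw), "ggplot")
  ev <- evaluate_folds(grade_from_predictions(tbl, 2), folded, beta = 2)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_member_entropy(tbl, beta = 0.6), "ggplot")
})
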