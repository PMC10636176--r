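test_that("tabular generator is reproducible with declared structure", {
  spec <- synthetic_spec(n_samples = 200, n_informative = 2, n_noise = 8,
                         class_sep = 6, seed = 1)
  d1 <- make_tabular(spec)
  d2 <- make_tabular(spec)
  expect_identical(d1, d2)
  expect_identical(dim(d1$data), c(200L, 11L))
  expect_identical(unname(d1$truth_mask),
                   c(1L, 1L, rep(0L, 8)))
  expect_identical(levels(d1$data$class), c("c1", "c2"))
})

test_that("declared signal is recoverable and noise carries none", {
  d <- make_tabular(synthetic_spec(n_samples = 200, n_informative = 2,
                                   n_noise = 8, class_sep = 6, seed = 2))
  x <- as.matrix(d$data[, 1:10]); y <- d$data$class
  err_inf <- withr::with_seed(1, cv_error(x, y, d$truth_mask))
  expect_lt(err_inf, 0.05)
  noise_mask <- 1L - d$truth_mask
  err_noise <- withr::with_seed(1, cv_error(x, y, noise_mask))
  expect_equal(err_noise, 0.5, tolerance = 0.1)
})

test_that("true mask beats random masks of equal size", {
  d <- make_tabular(synthetic_spec(n_samples = 150, n_informative = 2,
                                   n_noise = 8, class_sep = 6, seed = 3))
  x <- as.matrix(d$data[, 1:10]); y <- d$data$class
  folds <- withr::with_seed(5, stratified_folds(y, 10))
  err_true <- cv_error(x, y, d$truth_mask, folds = folds)
  err_rand <- withr::with_seed(6, vapply(1:20, function(i) {
    m <- integer(10); m[sample.int(10, 2)] <- 1L
    cv_error(x, y, m, folds = folds)
  }, numeric(1)))
  # the planted subset beats random equal-size subsets on average (a random
  # draw occasionally hits part of the signal, so the comparison is to the
  # mean, per the 20-draw protocol)
  expect_lt(err_true, mean(err_rand))
  expect_lte(err_true, stats::quantile(err_rand, 0.25) + 0.01)
})

test_that("redundant columns are label-linked through the informative ones", {
  d <- make_tabular(synthetic_spec(n_samples = 120, n_informative = 2,
                                   n_redundant = 2, n_noise = 2,
                                   class_sep = 6, seed = 4))
  expect_identical(unname(d$truth_mask), c(1L, 1L, 1L, 1L, 0L, 0L))
  x <- as.matrix(d$data[, 1:6]); y <- d$data$class
  red_only <- c(0L, 0L, 1L, 1L, 0L, 0L)
  err_red <- withr::with_seed(1, cv_error(x, y, red_only))
  expect_lt(err_red, 0.35)  # informative signal leaks through
})

test_that("a spec with no informative columns yields a null dataset", {
  d <- make_tabular(synthetic_spec(n_samples = 100, n_informative = 0,
                                   n_noise = 5, seed = 5))
  expect_identical(sum(d$truth_mask), 0L)
  x <- as.matrix(d$data[, 1:5]); y <- d$data$class
  err <- withr::with_seed(2, cv_error(x, y, rep(1L, 5)))
  expect_equal(err, 0.5, tolerance = 0.12)
  expect_error(synthetic_spec(n_informative = 0, n_redundant = 2,
                              n_noise = 2), "redundant")
})

test_that("feature-table generator mimics rectified deep activations", {
  ft <- make_feature_table(c(159, 77), feat_dim = 300,
                           informative_frac = 0.05, seed = 1)
  expect_identical(dim(ft$features), c(236L, 300L))
  expect_identical(as.vector(table(ft$labels)), c(159L, 77L))
  expect_true(all(ft$features >= 0))
  expect_identical(length(ft$informative), 15L)
  ft2 <- make_feature_table(c(159, 77), feat_dim = 300,
                            informative_frac = 0.05, seed = 1)
  expect_identical(ft, ft2)
})

test_that("zero informative fraction means no class signal", {
  centroid_gap <- function(x, lbl) {
    d <- colMeans(x[lbl == levels(lbl)[1], ]) -
      colMeans(x[lbl == levels(lbl)[2], ])
    sqrt(sum(d^2))
  }
  ft0 <- make_feature_table(c(60, 60), feat_dim = 100,
                            informative_frac = 0, seed = 2)
  obs0 <- centroid_gap(ft0$features, ft0$labels)
  perms <- withr::with_seed(3, vapply(1:199, function(i) {
    centroid_gap(ft0$features, sample(ft0$labels))
  }, numeric(1)))
  # without informative columns the observed gap sits inside the permutation
  # distribution (up to a small slack for the finite permutation count) ...
  expect_lt(obs0, max(perms) * 1.05)
  expect_gt(obs0, min(perms) * 0.95)
  # ... while planted signal pushes the gap far outside it
  ft1 <- make_feature_table(c(60, 60), feat_dim = 100,
                            informative_frac = 0.2, seed = 2)
  obs1 <- centroid_gap(ft1$features, ft1$labels)
  expect_gt(obs1, max(perms) * 1.5)
})

test_that("toy image trees are reproducible and class-structured", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_toy_images(3, dir = dir1, size = 48, seed = 7)
  make_toy_images(3, dir = dir2, size = 48, seed = 7)
  f1 <- list.files(dir1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(dir2, recursive = TRUE, full.names = TRUE)
  expect_length(f1, 6)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
  # diseased images are darker on average (lesions absorb light)
  b <- preprocess_images(dir1, target_size = 48)
  means <- vapply(b$images, mean, numeric(1))
  expect_lt(mean(means[b$labels == "diseased"]),
            mean(means[b$labels == "healthy"]))
})
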