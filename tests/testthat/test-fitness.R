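test_that("euclidean distance satisfies the metric basics", {
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
  expect_identical(euclidean_distance(c(0, 1), c(1, 0)),
                   euclidean_distance(c(1, 0), c(0, 1)))
  expect_error(euclidean_distance(1:2, 1:3), "equal length")
})

test_that("knn prediction takes the majority of the k nearest", {
  tr <- rbind(c(0, 0), c(1, 1))
  expect_identical(as.character(knn_predict(tr, c("A", "B"), c(0.1, 0),
                                            k = 1)), "A")
  # k = all training points -> global majority class
  tr2 <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6), c(5, 7))
  y2 <- c("A", "A", "B", "B", "B")
  expect_identical(as.character(knn_predict(tr2, y2, c(2, 2), k = 5)), "B")
  # hand-enumerated 5-point case: neighbours of (0.2, 0.5) at k = 3 are
  # (0.4,0.5)->B, (0,0)->A, (0,1)->A; majority A
  tr3 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0.4, 0.5))
  y3 <- c("A", "A", "B", "B", "B")
  expect_identical(as.character(knn_predict(tr3, y3, c(0.2, 0.5), k = 3)),
                   "A")
  expect_error(knn_predict(tr, c("A", "B"), c(0, 0), k = 3), "k cannot")
  expect_error(knn_predict(tr[0, , drop = FALSE], character(0), c(0, 0)),
               "empty")
})

test_that("knn agrees with an independent implementation when no ties occur", {
  skip_if_not_installed("class")
  withr::with_seed(11, {
    tr <- matrix(rnorm(200), 100, 2)
    y <- factor(rep(c("a", "b"), 50))
    tr[y == "b", ] <- tr[y == "b", ] + 2
    qu <- matrix(rnorm(60), 30, 2) + 1
    mine <- knn_predict(tr, y, qu, k = 5)
    ref <- class::knn(tr, qu, y, k = 5)
    expect_identical(as.character(mine), as.character(ref))
  })
})

test_that("knn class ties break by summed distance then class index", {
  # two neighbours per class at k = 4; class 'a' is closer in total
  tr <- rbind(c(0, 0), c(0, 0.1), c(0, 0.6), c(0, 0.7))
  y <- factor(c("a", "a", "b", "b"))
  expect_identical(as.character(knn_predict(tr, y, c(0, 0), k = 4)), "a")
  # perfectly symmetric -> lowest class index (levels order) wins
  tr2 <- rbind(c(-1, 0), c(-2, 0), c(1, 0), c(2, 0))
  y2 <- factor(c("z", "z", "q", "q"), levels = c("q", "z"))
  expect_identical(as.character(knn_predict(tr2, y2, c(0, 0), k = 4)), "q")
})

test_that("stratified folds preserve class balance and shrink when needed", {
  y <- factor(rep(c("a", "b"), c(40, 60)))
  f <- withr::with_seed(1, stratified_folds(y, 10))
  expect_setequal(unique(f), 1:10)
  tab <- table(f, y)
  expect_true(all(tab[, "a"] == 4))
  expect_true(all(tab[, "b"] == 6))
  y2 <- factor(rep(c("a", "b"), c(4, 60)))
  expect_warning(f2 <- withr::with_seed(1, stratified_folds(y2, 10)),
                 "reducing fold count")
  expect_identical(max(f2), 4L)
  expect_error(stratified_folds(factor(rep("a", 10)), 2), "two classes")
})

test_that("cv error separates separable data and is null on shuffled labels", {
  d <- two_clouds(n = 100, sep = 10, noise_cols = 2, seed = 5)
  x <- as.matrix(d[, 1:4]); y <- d$class
  err <- withr::with_seed(1, cv_error(x, y, c(1L, 1L, 0L, 0L)))
  expect_lt(err, 0.05)
  # shuffled labels: error near one half
  y_sh <- withr::with_seed(2, sample(y))
  err_null <- withr::with_seed(3, cv_error(x, y_sh, c(1L, 1L, 0L, 0L)))
  expect_equal(err_null, 0.5, tolerance = 0.1)
  # determinism given the seed / fold assignment
  e1 <- withr::with_seed(7, cv_error(x, y, c(1L, 1L, 1L, 0L)))
  e2 <- withr::with_seed(7, cv_error(x, y, c(1L, 1L, 1L, 0L)))
  expect_identical(e1, e2)
})

test_that("cv error is invariant to consistent column permutation", {
  d <- two_clouds(n = 80, sep = 3, noise_cols = 3, seed = 9)
  x <- as.matrix(d[, 1:5]); y <- d$class
  mask <- c(1L, 0L, 1L, 1L, 0L)
  folds <- withr::with_seed(4, stratified_folds(y, 10))
  perm <- c(4, 1, 5, 2, 3)
  e1 <- cv_error(x, y, mask, folds = folds)
  e2 <- cv_error(x[, perm], y, mask[perm], folds = folds)
  expect_identical(e1, e2)
})

test_that("the wrapper fitness combines error and subset fraction", {
  expect_equal(selection_fitness(0, 10, 10)$total, 0.1)
  expect_equal(selection_fitness(1, 10, 10)$total, 1)
  expect_equal(selection_fitness(0.3, 5, 10)$total, 0.32)
  f <- selection_fitness(0.2, 3, 9, fitness_config(alpha_w = 0.8))
  expect_equal(f$total, 0.8 * 0.2 + 0.2 * (3 / 9))
  # monotone in both arguments
  errs <- seq(0, 1, by = 0.1)
  tot_err <- vapply(errs, function(e) selection_fitness(e, 5, 10)$total,
                    numeric(1))
  expect_true(all(diff(tot_err) > 0))
  tot_card <- vapply(1:10, function(k) selection_fitness(0.3, k, 10)$total,
                     numeric(1))
  expect_true(all(diff(tot_card) > 0))
  expect_error(selection_fitness(0.1, 0, 10), "n_selected")
  expect_error(selection_fitness(0.1, 11, 10), "n_selected")
})

test_that("fitness config enforces alpha + beta = 1", {
  cfg <- fitness_config(alpha_w = 0.7)
  expect_equal(cfg$alpha_w + cfg$beta_w, 1)
  expect_identical(fitness_config()$k_neighbors, 5L)
  expect_identical(fitness_config()$n_folds, 10L)
  expect_error(fitness_config(alpha_w = 1.2))
})
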