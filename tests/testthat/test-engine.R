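test_that("exploration-parameter schedules match their closed forms", {
  expect_identical(a_linear(0, 20), 2)
  expect_identical(a_linear(10, 20), 1)
  expect_identical(a_linear(20, 20), 0)
  expect_identical(a_exponential(0, 5, 20), 2)
  expect_equal(a_exponential(4, 5, 20), 0.735759, tolerance = 1e-6)
  expect_equal(a_exponential(20, 5, 20), 0.013476, tolerance = 1e-4)
  expect_error(a_linear(-1, 20), "t must lie")
  expect_error(a_linear(21, 20), "t must lie")
  expect_error(a_exponential(1, 5, 0), "t_max")
})

test_that("both schedules start at 2 and strictly decrease", {
  for (t_max in c(5, 20, 100)) {
    lin <- vapply(0:t_max, a_linear, numeric(1), t_max = t_max)
    expc <- vapply(0:t_max, a_exponential, numeric(1), s = 5, t_max = t_max)
    expect_identical(lin[1], 2)
    expect_identical(expc[1], 2)
    expect_true(all(diff(lin) < 0))
    expect_true(all(diff(expc) < 0))
    expect_true(all(expc > 0 & expc <= 2))
  }
})

test_that("coefficient pairs respect their component ranges", {
  withr::with_seed(1, {
    p0 <- coefficient_pair(0, 50)
    expect_identical(p0$A, rep(0, 50))
    draws <- replicate(200, coefficient_pair(2, 50), simplify = FALSE)
    A <- unlist(lapply(draws, `[[`, "A"))
    C <- unlist(lapply(draws, `[[`, "C"))
    expect_true(all(A >= -2 & A <= 2))
    expect_true(all(C >= 0 & C <= 2))
    # the draws actually span the ranges
    expect_lt(min(A), -1.9); expect_gt(max(A), 1.9)
    expect_lt(min(C), 0.1); expect_gt(max(C), 1.9)
  })
  p1 <- withr::with_seed(7, coefficient_pair(1.5, 10))
  p2 <- withr::with_seed(7, coefficient_pair(1.5, 10))
  expect_identical(p1, p2)
})

test_that("encircling update follows D = |C*Xp - X|, X' = Xp - A*D", {
  pair <- list(A = c(0.5, 0.5), C = c(1, 1), a = 1)
  expect_equal(encircle_update(c(1, 1), c(2, 2), pair), c(1.5, 1.5))
  pair0 <- list(A = c(0, 0), C = c(0.3, 1.7), a = 1)
  expect_equal(encircle_update(c(5, -1), c(2, 2), pair0), c(2, 2))
  pair1 <- list(A = c(0.8, 0.8), C = c(1, 1), a = 1)
  expect_equal(encircle_update(c(2, 2), c(2, 2), pair1), c(2, 2))
  expect_error(encircle_update(c(1, 1, 1), c(2, 2), pair), "dimension")
})

test_that("leader candidates reduce to the leader positions when A = 0", {
  leaders <- list(alpha = list(position = c(1, 0)),
                  beta  = list(position = c(0, 1)),
                  delta = list(position = c(1, 1)))
  zero <- list(A = c(0, 0), C = c(1, 1), a = 0)
  cand <- leader_candidates(c(0.5, 0.5), leaders, list(zero, zero, zero))
  expect_equal(cand$X1, c(1, 0))
  expect_equal(cand$X2, c(0, 1))
  expect_equal(cand$X3, c(1, 1))
  # hand-derived case: X=(0,0), X_alpha=(2,2), C1=A1=(1,1) -> X1 = (0,0)
  leaders1 <- list(alpha = list(position = c(2, 2)),
                   beta = list(position = c(2, 2)),
                   delta = list(position = c(2, 2)))
  one <- list(A = c(1, 1), C = c(1, 1), a = 2)
  cand1 <- leader_candidates(c(0, 0), leaders1, list(one, zero, zero))
  expect_equal(cand1$X1, c(0, 0))
  expect_equal(cand1$X2, c(2, 2))
})

test_that("weighted aggregation generalizes the equal-thirds mean", {
  expect_equal(aggregate_mean(c(1, 2), c(3, 4), c(5, 6)), c(3, 4))
  w <- list(w1 = 1, w2 = 0, w3 = 0)
  expect_equal(aggregate_weighted(c(1, 0), c(9, 9), c(9, 9), w), c(1, 0))
  w2 <- list(w1 = 0.5, w2 = 0.3, w3 = 0.2)
  expect_equal(aggregate_weighted(c(1, 0), c(0, 1), c(1, 1), w2),
               c(0.7, 0.5))
  withr::with_seed(5, {
    third <- list(w1 = 1 / 3, w2 = 1 / 3, w3 = 1 / 3)
    for (i in 1:100) {
      X <- matrix(rnorm(15), 3)
      expect_equal(aggregate_weighted(X[1, ], X[2, ], X[3, ], third),
                   aggregate_mean(X[1, ], X[2, ], X[3, ]))
    }
  })
  expect_error(aggregate_mean(1:2, 1:3, 1:2), "equal dimensionality")
})

test_that("variable weight schedule has the right limits and normalization", {
  w0 <- weight_schedule(0)
  expect_identical(c(w0$w1, w0$w2, w0$w3), c(1, 0, 0))
  winf <- weight_schedule(1e9)
  expect_equal(winf$w1, 1 / 3, tolerance = 1e-4)
  expect_equal(winf$w2, 1 / 3, tolerance = 1e-4)
  expect_equal(winf$w3, 1 / 3, tolerance = 1e-4)
  w1 <- weight_schedule(1)
  expect_equal(w1$w1, 0.8166, tolerance = 1e-3)
  expect_equal(w1$w2, 0.2666, tolerance = 1e-3)
  expect_equal(w1$w3, -0.0832, tolerance = 1e-3)  # negative, as defined
  its <- unique(round(10^seq(0, 6, length.out = 1000)))
  ws <- vapply(its, function(i) {
    w <- weight_schedule(i)
    c(w$w1, w$w2, w$w3)
  }, numeric(3))
  expect_true(all(abs(colSums(ws) - 1) < 1e-12))
  expect_true(all(diff(ws[1, ]) <= 1e-12))  # w1 non-increasing
  expect_error(weight_schedule(-1), "non-negative")
  wc <- weight_schedule(1, clamp_nonneg = TRUE)
  expect_identical(wc$w3, 0)
  expect_equal(wc$w1 + wc$w2, 1)
})

test_that("logistic map iterates correctly and rejects degenerate seeds", {
  expect_equal(logistic_map_sequence(0.2, 3),
               c(0.64, 0.9216, 0.28901376))
  expect_error(logistic_map_sequence(0.75, 3), "fixed")
  expect_error(logistic_map_sequence(0, 3), "strictly in")
  expect_error(logistic_map_sequence(1, 3), "strictly in")
  expect_identical(logistic_map_sequence(0.2, 50),
                   logistic_map_sequence(0.2, 50))
  x <- logistic_map_sequence(0.37, 1e4, burn_in = 100)
  expect_true(all(x >= 0 & x <= 1))
  # invariant density is beta(1/2,1/2): edges denser than the middle
  edge <- mean(x < 0.1 | x > 0.9)
  centre <- mean(x > 0.45 & x < 0.55)
  expect_gt(edge, 2 * centre)
})

test_that("swarm initialization fills bounds reproducibly", {
  cfg <- engine_config(n_agents = 5, dim = 9, t_max = 20)
  sw <- withr::with_seed(3, initialize_swarm(cfg))
  expect_length(sw, 5)
  for (a in sw) {
    expect_length(a$position, 9)
    expect_true(all(a$position > 0 & a$position < 1))
    expect_identical(a$fitness, Inf)
  }
  sw2 <- withr::with_seed(3, initialize_swarm(cfg))
  expect_identical(sw, sw2)
  cfgu <- engine_config(n_agents = 6, dim = 4, t_max = 5, init = "uniform",
                        bounds = c(-2, 3))
  swu <- withr::with_seed(1, initialize_swarm(cfgu))
  pos <- do.call(rbind, lapply(swu, `[[`, "position"))
  expect_true(all(pos >= -2 & pos <= 3))
})

test_that("engine config validates its invariants", {
  expect_error(engine_config(n_agents = 3, dim = 5, t_max = 10), "alpha")
  expect_error(engine_config(n_agents = 5, dim = 5, t_max = 10,
                             bounds = c(1, 1)), "strictly below")
  cfg <- engine_config(n_agents = 5, dim = 2, t_max = 0)
  expect_identical(cfg$t_max, 0L)
})

test_that("both optimizers minimize the sphere function", {
  # dim 10, 200 iterations, 10 seeds; >= 9/10 reach < 1e-2. The modified
  # schedule's decay rate is proportional to swarm size, so it runs at its
  # calibrated swarm size (5); standard GWO runs with 30 agents.
  sphere <- function(x) sum(x^2)
  for (preset in list(
    list(a = "linear", agg = "mean", init = "uniform", s = 30),
    list(a = "exponential", agg = "variable_weights", init = "chaotic",
         s = 5))) {
    cfg <- engine_config(n_agents = preset$s, dim = 10, t_max = 200,
                         a_schedule = preset$a, aggregation = preset$agg,
                         init = preset$init, bounds = c(-1, 1))
    hits <- sum(vapply(1:10, function(s) {
      gwo_optimize(sphere, cfg, seed = s)$best_fitness < 1e-2
    }, logical(1)))
    expect_gte(hits, 9)
  }
})

test_that("positions stay inside bounds through whole optimization runs", {
  box <- function(lo, hi) {
    cfg <- engine_config(n_agents = 5, dim = 4, t_max = 30,
                         bounds = c(lo, hi))
    res <- gwo_optimize(function(x) sum((x - lo)^2), cfg, seed = 2)
    expect_true(all(res$best_position >= lo & res$best_position <= hi))
    expect_true(all(diff(res$convergence) <= 0))
    expect_length(res$convergence, 31)
  }
  box(0, 1)
  box(-5, 5)
})
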