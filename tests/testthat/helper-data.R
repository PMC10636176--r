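# Small fixtures built in code, shared across test files.

# Two well-separated Gaussian clouds in 2D plus optional noise columns.
two_clouds <- function(n = 100, sep = 10, noise_cols = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("a", "b"), length.out = n))
    x1 <- ifelse(y == "a", 0, sep) + rnorm(n)
    x2 <- ifelse(y == "a", 0, sep) + rnorm(n)
    d <- tibble::tibble(x1 = x1, x2 = x2)
    if (noise_cols > 0) {
      for (j in seq_len(noise_cols)) d[[paste0("n", j)]] <- rnorm(n)
    }
    d$class <- y
    d
  })
}

# Exhaustive fitness minimum over all non-empty masks of a small dataset,
# computed by direct enumeration with the same fold assignment the wrapper
# run used (reconstructed from its seed substream).
exhaustive_optimum <- function(data, class_col = "class", seed,
                               fitness = fitness_config()) {
  parts <- wolfselect:::split_xy(data, class_col)
  folds <- withr::with_seed(wolfselect:::substream(as.integer(seed), 2L),
                            stratified_folds(parts$y, fitness$n_folds))
  d <- ncol(parts$x)
  stopifnot(d <= 12)
  best <- Inf; best_mask <- NULL
  for (code in seq_len(2^d - 1)) {
    mask <- as.integer(intToBits(code)[seq_len(d)])
    err <- cv_error(parts$x, parts$y, mask, fitness, folds = folds)
    fit <- selection_fitness(err, sum(mask), d, fitness)$total
    if (fit < best) {
      best <- fit
      best_mask <- mask
    }
  }
  list(fitness = best, mask = best_mask)
}

# Half a unit in the last printed decimal place, floored at 0.01: values
# printed with one decimal carry +-0.05 of rounding slack, two decimals
# +-0.01 (the floor).
printed_tol <- function(x) {
  dec <- vapply(x, function(v) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(v, trim = TRUE)))
    nchar(s)
  }, integer(1))
  pmax(0.5 * 10^(-dec), 0.01)
}
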