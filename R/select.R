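#' Wrapper feature selection with GWO / MGWO
#'
#' Runs the binary grey-wolf wrapper on a labelled feature table. Agents move
#' in the continuous unit hypercube; at every evaluation each position is
#' binarized through the S-shaped transfer function into a feature mask,
#' empty masks are repaired, and the mask is scored by the KNN
#' cross-validation fitness ([cv_error()] weighted with the subset fraction,
#' see [selection_fitness()]). The alpha wolf's mask is returned together
#' with the best-so-far convergence trace.
#'
#' `algorithm = "mgwo"` enables the three modifications together
#' (exponential decay of `a`, variable leader weights, chaotic logistic-map
#' initialization); `algorithm = "gwo"` is the standard optimizer (linear
#' decay, equal-thirds aggregation, uniform initialization). Pass an explicit
#' `engine` to mix the switches freely.
#'
#' Two swarm representations are available. The default, `"mask"`, is the
#' standard binary grey-wolf wiring: each agent's position is its binary
#' mask, the leader-driven update arithmetic produces a continuous
#' intermediate which is clamped and re-binarized into the next mask, so a
#' converged swarm genuinely exploits the neighbourhood of good masks. The
#' `"continuous"` representation keeps a real-valued position per agent
#' across iterations and draws a fresh stochastic mask from it at every
#' evaluation; it explores more but cannot concentrate on a specific mask.
#' Under the `"mask"` representation the driver defaults to the
#' `"conventional"` transfer direction (bit = 1 when `R < x_s`), because the
#' mirrored `"as_printed"` direction would invert a converged mask at each
#' step; both remain selectable.
#'
#' @param data A data frame with numeric feature columns and one class
#'   column.
#' @param class_col Name of the class column (default `"class"`).
#' @param algorithm `"mgwo"` (default) or `"gwo"`.
#' @param n_agents,t_max Swarm size and iteration budget (defaults 5 and 20,
#'   the published protocol).
#' @param fitness A [fitness_config()].
#' @param engine Optional [engine_config()] overriding the `algorithm`
#'   preset (its `dim` must equal the number of feature columns).
#' @param convention Binarization convention, see [binarize()]; defaults to
#'   `"conventional"` under the `"mask"` representation and `"as_printed"`
#'   under `"continuous"`.
#' @param representation `"mask"` (binary swarm, default) or
#'   `"continuous"`; see Details.
#' @param seed Integer seed; one seed drives the whole run (initialization,
#'   fold assignment, binarization) through fixed substreams.
#' @return An object of class `"gwo_selection"`: a list with `best_mask`
#'   (named 0/1 integer vector), `best_fitness`, `best_error`,
#'   `convergence`, `n_evaluations`, `seed`, `algorithm`, and the configs
#'   used. Use [tidy()][generics::tidy] for a per-feature tibble,
#'   [glance()][generics::glance] for a one-row summary, and
#'   `autoplot()` for the convergence curve.
#' @export
#' @examples
#' d <- make_tabular(synthetic_spec(n_samples = 60, n_informative = 2,
#'                                  n_noise = 3, seed = 1))
#' res <- select_features(d$data, t_max = 5, seed = 1)
#' glance(res)
select_features <- function(data, class_col = "class",
                            algorithm = c("mgwo", "gwo"),
                            n_agents = 5L, t_max = 20L,
                            fitness = fitness_config(),
                            engine = NULL,
                            convention = NULL,
                            representation = c("mask", "continuous"),
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  representation <- match.arg(representation)
  if (is.null(convention)) {
    convention <- if (representation == "mask") "conventional"
                  else "as_printed"
  }
  convention <- match.arg(convention, c("as_printed", "conventional"))
  parts <- split_xy(data, class_col)
  x <- parts$x; y <- parts$y
  d <- ncol(x)
  if (d < 2L) stop("need at least 2 feature columns", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("need at least 2 classes in the data", call. = FALSE)
  }
  if (is.null(engine)) {
    engine <- algorithm_engine(algorithm, n_agents, d, t_max)
  }
  stopifnot(inherits(engine, "engine_config"), engine$dim == d)
  stopifnot(inherits(fitness, "fitness_config"))
  seed <- as.integer(seed)

  folds <- withr::with_seed(substream(seed, 2L),
                            stratified_folds(y, fitness$n_folds))

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    n_eval <<- n_eval + 1L
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    err <- cv_error(x, y, mask, fitness, folds = folds)
    val <- selection_fitness(err, sum(mask), d, fitness)
    cache[[key]] <- val
    val
  }

  withr::local_seed(substream(seed, 1L))
  agents <- initialize_swarm(engine)
  for (i in seq_along(agents)) {
    m <- repair_mask(binarize(agents[[i]]$position, convention))
    fv <- eval_mask(m)
    agents[[i]]$mask <- m
    if (representation == "mask") agents[[i]]$position <- as.numeric(m)
    agents[[i]]$fitness <- fv$total
    agents[[i]]$error <- fv$error_rate
  }
  leaders <- rank_leaders(agents)
  best <- leaders$alpha
  conv <- numeric(engine$t_max + 1L)
  conv[1L] <- best$fitness

  if (engine$t_max > 0L) {
    for (t in seq_len(engine$t_max)) {
      a <- a_value(engine, t)
      w <- if (engine$aggregation == "variable_weights") {
        weight_schedule(t, clamp_nonneg = engine$clamp_w3_nonneg)
      }
      for (i in seq_along(agents)) {
        pairs <- replicate(3, coefficient_pair(a, d), simplify = FALSE)
        cand <- leader_candidates(agents[[i]]$position, leaders, pairs)
        newpos <- if (is.null(w)) {
          aggregate_mean(cand$X1, cand$X2, cand$X3, bounds = engine$bounds)
        } else {
          aggregate_weighted(cand$X1, cand$X2, cand$X3, w,
                             bounds = engine$bounds)
        }
        m <- repair_mask(binarize(newpos, convention))
        fv <- eval_mask(m)
        agents[[i]]$position <- if (representation == "mask") as.numeric(m)
                                else newpos
        agents[[i]]$mask <- m
        agents[[i]]$fitness <- fv$total
        agents[[i]]$error <- fv$error_rate
      }
      leaders <- merge_leaders(leaders, rank_leaders(agents))
      if (leader_beats(leaders$alpha, best)) best <- leaders$alpha
      conv[t + 1L] <- best$fitness
    }
  }

  mask <- best$mask
  names(mask) <- colnames(x)
  structure(
    list(best_mask = mask, best_fitness = best$fitness,
         best_error = best$error, convergence = conv,
         n_evaluations = n_eval, seed = seed, algorithm = algorithm,
         convention = convention, representation = representation,
         engine = engine, fitness = fitness,
         n_samples = nrow(x), n_features = d),
    class = "gwo_selection"
  )
}

leader_beats <- function(a, b) {
  a$fitness < b$fitness ||
    (a$fitness == b$fitness && sum(a$mask) < sum(b$mask))
}

algorithm_engine <- function(algorithm, n_agents, dim, t_max) {
  if (algorithm == "mgwo") {
    engine_config(n_agents = n_agents, dim = dim, t_max = t_max,
                  a_schedule = "exponential",
                  aggregation = "variable_weights", init = "chaotic")
  } else {
    engine_config(n_agents = n_agents, dim = dim, t_max = t_max,
                  a_schedule = "linear", aggregation = "mean",
                  init = "uniform")
  }
}

split_xy <- function(data, class_col) {
  data <- as.data.frame(data)
  if (!class_col %in% names(data)) {
    stop(sprintf("class column '%s' not found in the data", class_col),
         call. = FALSE)
  }
  y <- factor(data[[class_col]])
  x <- data[setdiff(names(data), class_col)]
  not_num <- !vapply(x, is.numeric, logical(1))
  if (any(not_num)) {
    stop("non-numeric feature columns: ",
         paste(names(x)[not_num], collapse = ", "), call. = FALSE)
  }
  list(x = as.matrix(x), y = y)
}

# Deterministic seed fan-out: one user seed, fixed substream index, result
# always a valid 32-bit integer seed.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6 * 7919 + k * 104729) %% 2147483629)
}

#' @export
print.gwo_selection <- function(x, ...) {
  cat(sprintf("<gwo_selection> %s, seed %d\n", toupper(x$algorithm), x$seed))
  cat(sprintf("  %d/%d features selected, fitness %.4f (CV error %.4f)\n",
              sum(x$best_mask), x$n_features, x$best_fitness, x$best_error))
  cat("  selected:", paste(names(x$best_mask)[x$best_mask == 1L],
                           collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a feature-selection result
#'
#' @param x A `"gwo_selection"` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per feature (`feature`,
#'   `selected`). `glance()`: a one-row tibble with the run summary
#'   (`algorithm`, `n_selected`, `n_features`, `best_fitness`, `cv_error`,
#'   `accuracy` as a percentage, `n_evaluations`, `seed`).
#' @method tidy gwo_selection
#' @export
tidy.gwo_selection <- function(x, ...) {
  tibble::tibble(feature = names(x$best_mask),
                 selected = x$best_mask == 1L)
}

#' @rdname tidy.gwo_selection
#' @method glance gwo_selection
#' @export
glance.gwo_selection <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_selected = sum(x$best_mask),
                 n_features = x$n_features,
                 best_fitness = x$best_fitness,
                 cv_error = x$best_error,
                 accuracy = 100 * (1 - x$best_error),
                 n_evaluations = x$n_evaluations,
                 seed = x$seed)
}

#' Convergence plot for a selection run
#'
#' @param object A `"gwo_selection"` object.
#' @param ... Unused.
#' @return A ggplot of the best-so-far fitness per iteration.
#' @method autoplot gwo_selection
#' @export
autoplot.gwo_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$convergence) - 1L,
                       best_fitness = object$convergence)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = sprintf("%s convergence (seed %d)",
                                  toupper(object$algorithm), object$seed)) +
    ggplot2::theme_minimal()
}

#' Multi-run selection benchmark
#'
#' Repeats [select_features()] `n_runs` times with consecutive seeds
#' (`seed0`, `seed0 + 1`, ...) and aggregates: mean selected-feature count,
#' mean final classification accuracy (100 x (1 - CV error of the best
#' mask)) and its standard deviation — one benchmark row per call.
#'
#' @param data,class_col As in [select_features()].
#' @param algorithm `"mgwo"` or `"gwo"`.
#' @param n_runs Number of independent runs (published protocol: 20).
#' @param seed0 Seed of the first run.
#' @param dataset_name Label used in the output row.
#' @param ... Passed on to [select_features()].
#' @return A one-row tibble: `dataset`, `algorithm`, `n_runs`,
#'   `mean_selected`, `mean_accuracy`, `std_accuracy`, plus a `runs`
#'   list-column holding the per-run [glance()][tidy.gwo_selection] rows.
#' @export
run_experiment <- function(data, class_col = "class",
                           algorithm = c("mgwo", "gwo"),
                           n_runs = 20L, seed0 = 1L,
                           dataset_name = "dataset", ...) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_runs >= 1)
  runs <- purrr::map(seq_len(n_runs) - 1L, function(i) {
    res <- select_features(data, class_col = class_col,
                           algorithm = algorithm, seed = seed0 + i, ...)
    glance(res)
  })
  runs <- dplyr::bind_rows(runs)
  tibble::tibble(
    dataset = dataset_name, algorithm = algorithm, n_runs = as.integer(n_runs),
    mean_selected = mean(runs$n_selected),
    mean_accuracy = mean(runs$accuracy),
    std_accuracy = if (n_runs > 1L) stats::sd(runs$accuracy) else 0,
    runs = list(runs)
  )
}
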