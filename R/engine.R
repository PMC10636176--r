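#' Engine configuration for the grey wolf optimizer
#'
#' Bundles and validates the parameters that drive the continuous grey wolf
#' search: the swarm size, search-space dimensionality, iteration budget, the
#' decay schedule of the exploration parameter `a`, how the three leader
#' candidates are aggregated into the new position, and how the initial swarm
#' is placed.
#'
#' The default configuration (`a_schedule = "exponential"`,
#' `aggregation = "variable_weights"`, `init = "chaotic"`) is the modified
#' grey wolf optimizer (MGWO); `a_schedule = "linear"`, `aggregation = "mean"`,
#' `init = "uniform"` recovers the standard GWO. The three modifications are
#' independently switchable.
#'
#' @param n_agents Number of search agents (wolves). Must be at least 4 when
#'   leader-based updates are used: alpha, beta, delta plus at least one omega.
#' @param dim Dimensionality of the search space.
#' @param t_max Total number of position-update iterations (>= 0; `t_max = 0`
#'   evaluates the initial swarm only).
#' @param a_schedule `"exponential"` for `a = 2 exp(-t s / t_max)` or
#'   `"linear"` for `a = 2 (1 - t / t_max)`.
#' @param aggregation `"variable_weights"` for the iteration-dependent leader
#'   weights, `"mean"` for the equal-thirds average.
#' @param init `"chaotic"` for logistic-map initialization, `"uniform"` for
#'   i.i.d. uniform draws within bounds.
#' @param bounds Length-2 numeric `c(lower, upper)` applied to every
#'   dimension, or a 2-row matrix (`dim` columns) of per-dimension bounds.
#' @param clamp_w3_nonneg If `TRUE`, a negative delta weight from the variable
#'   weight schedule is replaced by 0 and the triple renormalized so the
#'   combination is strictly convex. Default `FALSE`: the schedule is used
#'   exactly as defined even where `w3 < 0` (it happens at small iteration
#'   indices; see [weight_schedule()]).
#' @param chaotic_burn_in Number of logistic-map iterates discarded before the
#'   map output is used as coordinates (chaotic init only).
#'
#' @return An object of class `"engine_config"` (a validated list).
#' @export
#' @examples
#' engine_config(n_agents = 5, dim = 9, t_max = 20)
engine_config <- function(n_agents = 5L, dim, t_max = 20L,
                          a_schedule = c("exponential", "linear"),
                          aggregation = c("variable_weights", "mean"),
                          init = c("chaotic", "uniform"),
                          bounds = c(0, 1),
                          clamp_w3_nonneg = FALSE,
                          chaotic_burn_in = 100L) {
  a_schedule <- match.arg(a_schedule)
  aggregation <- match.arg(aggregation)
  init <- match.arg(init)
  stopifnot(is.numeric(n_agents), length(n_agents) == 1L, n_agents >= 1,
            is.numeric(dim), length(dim) == 1L, dim >= 1,
            is.numeric(t_max), length(t_max) == 1L, t_max >= 0)
  n_agents <- as.integer(n_agents); dim <- as.integer(dim)
  t_max <- as.integer(t_max)
  if (n_agents < 4L) {
    stop("n_agents must be >= 4: leader-based updates need alpha, beta, ",
         "delta and at least one omega", call. = FALSE)
  }
  b <- expand_bounds(bounds, dim)
  if (any(b[1, ] >= b[2, ])) {
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(
    list(n_agents = n_agents, dim = dim, t_max = t_max,
         a_schedule = a_schedule, aggregation = aggregation, init = init,
         bounds = b, clamp_w3_nonneg = isTRUE(clamp_w3_nonneg),
         chaotic_burn_in = as.integer(chaotic_burn_in)),
    class = "engine_config"
  )
}

expand_bounds <- function(bounds, dim) {
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2L, ncol(bounds) == dim)
    return(bounds)
  }
  stopifnot(is.numeric(bounds), length(bounds) == 2L)
  matrix(rep(as.numeric(bounds), dim), nrow = 2L,
         dimnames = list(c("lower", "upper"), NULL))
}

#' Exploration-parameter decay schedules
#'
#' The scalar `a` bounds the random coefficient `A` (`A` is uniform on
#' `[-a, a]` componentwise); `|A| > 1` drives exploration, `|A| < 1`
#' exploitation. Standard GWO shrinks `a` linearly from 2 to 0 over the run:
#' `a = 2 (1 - t / t_max)`. The modified schedule decays exponentially,
#' `a = 2 exp(-t s / t_max)` with `s` the swarm size, so exploitation starts
#' much earlier; both start at exactly 2 when `t = 0`.
#'
#' @param t Current iteration index, `0 <= t <= t_max`.
#' @param t_max Total iteration budget (>= 1).
#' @param s Swarm size (exponential schedule only, >= 1).
#' @return The scalar value of `a`.
#' @export
#' @examples
#' a_linear(10, 20)            # 1
#' a_exponential(0, 5, 20)     # 2
a_linear <- function(t, t_max) {
  check_t(t, t_max)
  2 * (1 - t / t_max)
}

#' @rdname a_linear
#' @export
a_exponential <- function(t, s, t_max) {
  check_t(t, t_max)
  stopifnot(is.numeric(s), length(s) == 1L, s >= 1)
  2 * exp(-t * s / t_max)
}

check_t <- function(t, t_max) {
  stopifnot(is.numeric(t), length(t) == 1L,
            is.numeric(t_max), length(t_max) == 1L)
  if (t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (t < 0 || t > t_max) {
    stop("iteration index t must lie in [0, t_max]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw a random coefficient pair
#'
#' Draws the stochastic coefficient vectors of the encircling equations:
#' `A = 2 a r1 - a` (uniform on `[-a, a]` per component) and `C = 2 r2`
#' (uniform on `[0, 2]`), with `r1`, `r2` i.i.d. uniform on `[0, 1]^dim`.
#' Fresh draws are made per agent, per leader, per dimension, per iteration.
#' Uses the current R random stream.
#'
#' @param a Current value of the exploration parameter, in `[0, 2]`.
#' @param dim Number of components.
#' @return A list with elements `A`, `C` (numeric vectors) and `a`.
#' @export
coefficient_pair <- function(a, dim) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0, a <= 2, dim >= 1)
  list(A = 2 * a * stats::runif(dim) - a, C = 2 * stats::runif(dim), a = a)
}

#' Encircling position update
#'
#' One prey-encircling step: `D = |C * Xp - X|` componentwise and the new
#' position is `Xp - A * D`, clamped to the search bounds.
#'
#' @param X Current position.
#' @param Xp Target (prey or leader) position, same length as `X`.
#' @param pair A coefficient pair from [coefficient_pair()].
#' @param bounds Optional 2-row bounds matrix; `NULL` skips clamping (used
#'   when a later aggregation step clamps instead).
#' @return The updated position vector.
#' @export
encircle_update <- function(X, Xp, pair, bounds = NULL) {
  d <- length(X)
  if (length(Xp) != d || length(pair$A) != d || length(pair$C) != d) {
    stop("dimension mismatch between position, target and coefficients",
         call. = FALSE)
  }
  D <- abs(pair$C * Xp - X)
  out <- Xp - pair$A * D
  if (!is.null(bounds)) out <- clamp(out, bounds)
  out
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1, ]), bounds[2, ])

#' Candidate positions towards the three leaders
#'
#' Computes the alpha-, beta- and delta-driven candidates `X1`, `X2`, `X3`,
#' each an encircling update towards the respective leader with its own fresh
#' coefficient pair.
#'
#' @param X Current position of the agent being updated.
#' @param leaders List with elements `alpha`, `beta`, `delta`, each holding a
#'   `position` vector (see [select_features()] internals or [gwo_optimize()]).
#' @param pairs List of three coefficient pairs, one per leader.
#' @return A list of three positions `X1`, `X2`, `X3` (unclamped; clamping
#'   happens after aggregation).
#' @export
leader_candidates <- function(X, leaders, pairs) {
  list(
    X1 = encircle_update(X, leaders$alpha$position, pairs[[1]]),
    X2 = encircle_update(X, leaders$beta$position,  pairs[[2]]),
    X3 = encircle_update(X, leaders$delta$position, pairs[[3]])
  )
}

#' Aggregate leader candidates
#'
#' `aggregate_mean()` is the standard equal-thirds average of the three
#' candidates. `aggregate_weighted()` applies a weight triple (see
#' [weight_schedule()]); with weights `(1/3, 1/3, 1/3)` it reduces exactly to
#' the mean.
#'
#' @param X1,X2,X3 Candidate positions of equal length.
#' @param w A weight triple as returned by [weight_schedule()] (or any list
#'   with `w1`, `w2`, `w3` summing to 1).
#' @param bounds Optional 2-row bounds matrix for clamping.
#' @return The aggregated (and clamped, if bounds given) position.
#' @export
aggregate_mean <- function(X1, X2, X3, bounds = NULL) {
  check_same_len(X1, X2, X3)
  out <- (X1 + X2 + X3) / 3
  if (!is.null(bounds)) out <- clamp(out, bounds)
  out
}

#' @rdname aggregate_mean
#' @export
aggregate_weighted <- function(X1, X2, X3, w, bounds = NULL) {
  check_same_len(X1, X2, X3)
  out <- w$w1 * X1 + w$w2 * X2 + w$w3 * X3
  if (!is.null(bounds)) out <- clamp(out, bounds)
  out
}

check_same_len <- function(X1, X2, X3) {
  if (length(X1) != length(X2) || length(X2) != length(X3)) {
    stop("candidate positions must have equal dimensionality", call. = FALSE)
  }
  invisible(TRUE)
}

#' Iteration-dependent leader weights
#'
#' The variable-weight aggregation replaces the equal-thirds leader average
#' with weights that follow the pack hierarchy: the alpha dominates early and
#' all three weights converge to 1/3 as the iteration index grows. With
#' `phi = arctan(it) / 2` and `theta = (2/pi) arccos(1/3) arctan(it)`:
#' `w1 = cos(theta)`, `w2 = sin(theta) cos(phi) / 2`, and `w3 = 1 - w1 - w2`
#' as the residual, so the triple sums to 1 exactly.
#'
#' Note that the residual `w3` is negative for small positive `it` (about
#' -0.083 at `it = 1`), so the combination is affine rather than convex
#' there; this is a property of the schedule as defined. Set
#' `clamp_nonneg = TRUE` to replace a negative `w3` with 0 and renormalize.
#'
#' @param it Iteration index (>= 0). The first position update of a run uses
#'   `it = 1`.
#' @param clamp_nonneg Replace negative `w3` by 0 and renormalize.
#' @return A list with `w1`, `w2`, `w3`, `it`, `phi`, `theta`.
#' @export
#' @examples
#' weight_schedule(0)    # (1, 0, 0)
#' weight_schedule(1e9)  # each ~ 1/3
weight_schedule <- function(it, clamp_nonneg = FALSE) {
  stopifnot(is.numeric(it), length(it) == 1L)
  if (it < 0) stop("iteration index must be non-negative", call. = FALSE)
  phi <- atan(it) / 2
  theta <- (2 / pi) * acos(1 / 3) * atan(it)
  w1 <- cos(theta)
  w2 <- 0.5 * sin(theta) * cos(phi)
  w3 <- 1 - w1 - w2
  if (isTRUE(clamp_nonneg) && w3 < 0) {
    w3 <- 0
    s <- w1 + w2
    w1 <- w1 / s
    w2 <- w2 / s
  }
  list(w1 = w1, w2 = w2, w3 = w3, it = it, phi = phi, theta = theta)
}

#' Logistic-map sequence
#'
#' Iterates the chaotic logistic map `x_{n+1} = mu x_n (1 - x_n)` with
#' `mu = 4` (the fully chaotic bifurcation value). Seeds at the fixed or
#' periodic points 0, 0.25, 0.5, 0.75, 1 collapse the sequence and are
#' rejected. The invariant density of the map at `mu = 4` is beta(1/2, 1/2):
#' iterates concentrate near 0 and 1, which is what makes it useful for
#' spreading an initial swarm.
#'
#' @param x0 Seed, strictly inside (0, 1) and not one of the forbidden
#'   values.
#' @param n Number of iterates to return.
#' @param burn_in Iterates discarded before the `n` returned ones.
#' @param mu Bifurcation coefficient (default and intended value 4).
#' @return Numeric vector of `n` map iterates (after burn-in).
#' @export
#' @examples
#' logistic_map_sequence(0.2, 3)  # 0.64 0.9216 0.28901376
logistic_map_sequence <- function(x0, n, burn_in = 0L, mu = 4) {
  stopifnot(is.numeric(x0), length(x0) == 1L, n >= 1, burn_in >= 0)
  forbidden <- c(0, 0.25, 0.5, 0.75, 1)
  if (x0 <= 0 || x0 >= 1 || x0 %in% forbidden) {
    stop("logistic-map seed must lie strictly in (0, 1) and avoid the ",
         "fixed/periodic points {0, 0.25, 0.5, 0.75, 1}", call. = FALSE)
  }
  total <- n + burn_in
  out <- numeric(total)
  x <- x0
  for (i in seq_len(total)) {
    x <- mu * x * (1 - x)
    out[i] <- x
  }
  out[(burn_in + 1):total]
}

#' Initialize a swarm of agents
#'
#' Places `n_agents` positions inside the bounds. In `"chaotic"` mode each
#' agent gets its own logistic map, seeded from a uniform draw on
#' (0.01, 0.99) avoiding the map's degenerate seeds, with `chaotic_burn_in`
#' iterates discarded; the next `dim` iterates (which live in (0, 1)) are
#' rescaled to the bounds. In `"uniform"` mode coordinates are i.i.d. uniform
#' within bounds. Fitness is initialized to `Inf`. Uses the current R random
#' stream.
#'
#' @param cfg An [engine_config()].
#' @return A list of agents, each a list with `position` (numeric vector),
#'   `fitness` (`Inf`) and `id`.
#' @export
initialize_swarm <- function(cfg) {
  stopifnot(inherits(cfg, "engine_config"))
  lo <- cfg$bounds[1, ]; hi <- cfg$bounds[2, ]
  lapply(seq_len(cfg$n_agents), function(i) {
    u <- if (cfg$init == "chaotic") {
      x0 <- draw_chaotic_seed()
      logistic_map_sequence(x0, cfg$dim, burn_in = cfg$chaotic_burn_in)
    } else {
      stats::runif(cfg$dim)
    }
    list(position = lo + u * (hi - lo), fitness = Inf, id = i)
  })
}

draw_chaotic_seed <- function() {
  forbidden <- c(0.25, 0.5, 0.75)
  repeat {
    x0 <- stats::runif(1, 0.01, 0.99)
    if (!x0 %in% forbidden) return(x0)
  }
}

a_value <- function(cfg, t) {
  switch(cfg$a_schedule,
         linear = a_linear(t, cfg$t_max),
         exponential = a_exponential(t, cfg$n_agents, cfg$t_max))
}

#' Rank a swarm and pick the leaders
#'
#' Orders agents by fitness (lower is better). Ties break by mask
#' cardinality when agents carry a `mask` element (fewer selected features
#' ranks higher, matching the feature-minimization objective), then by agent
#' id. Returns the alpha, beta, delta triple.
#'
#' @param agents List of agent states (each with `fitness`, `id`, optionally
#'   `mask`).
#' @return A list with `alpha`, `beta`, `delta`.
#' @keywords internal
rank_leaders <- function(agents) {
  fit <- vapply(agents, `[[`, numeric(1), "fitness")
  card <- vapply(agents, function(a) {
    if (is.null(a$mask)) 0 else sum(a$mask)
  }, numeric(1))
  id <- vapply(agents, `[[`, integer(1), "id")
  o <- order(fit, card, id)
  list(alpha = agents[[o[1]]],
       beta  = agents[[o[min(2L, length(o))]]],
       delta = agents[[o[min(3L, length(o))]]])
}

#' Minimize a continuous objective with GWO/MGWO
#'
#' The continuous optimizer underlying the feature-selection wrapper: runs
#' the full leader-driven position-update loop on an arbitrary objective.
#' Mostly useful for checking the engine on analytic test functions (e.g.
#' the sphere function).
#'
#' @param fn Objective `function(x) -> scalar`, minimized.
#' @param cfg An [engine_config()].
#' @param seed Integer seed for reproducibility.
#' @return A list with `best_position`, `best_fitness` and `convergence`
#'   (best-so-far fitness, length `t_max + 1`).
#' @export
#' @examples
#' cfg <- engine_config(n_agents = 10, dim = 3, t_max = 50)
#' res <- gwo_optimize(function(x) sum(x^2), cfg, seed = 1)
#' res$best_fitness
gwo_optimize <- function(fn, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "engine_config"), is.function(fn))
  withr::local_seed(as.integer(seed))
  agents <- initialize_swarm(cfg)
  for (i in seq_along(agents)) {
    agents[[i]]$fitness <- fn(agents[[i]]$position)
  }
  leaders <- rank_leaders(agents)
  best <- leaders$alpha
  conv <- numeric(cfg$t_max + 1L)
  conv[1L] <- best$fitness
  if (cfg$t_max > 0L) {
    for (t in seq_len(cfg$t_max)) {
      a <- a_value(cfg, t)
      w <- if (cfg$aggregation == "variable_weights") {
        weight_schedule(t, clamp_nonneg = cfg$clamp_w3_nonneg)
      }
      for (i in seq_along(agents)) {
        pairs <- replicate(3, coefficient_pair(a, cfg$dim), simplify = FALSE)
        cand <- leader_candidates(agents[[i]]$position, leaders, pairs)
        newpos <- if (is.null(w)) {
          aggregate_mean(cand$X1, cand$X2, cand$X3, bounds = cfg$bounds)
        } else {
          aggregate_weighted(cand$X1, cand$X2, cand$X3, w,
                             bounds = cfg$bounds)
        }
        agents[[i]]$position <- newpos
        agents[[i]]$fitness <- fn(newpos)
      }
      cur <- rank_leaders(agents)
      leaders <- merge_leaders(leaders, cur)
      if (leaders$alpha$fitness < best$fitness) best <- leaders$alpha
      conv[t + 1L] <- best$fitness
    }
  }
  list(best_position = best$position, best_fitness = best$fitness,
       convergence = conv)
}

# Keep best-so-far alpha/beta/delta: pool previous leaders with the current
# swarm's leaders, drop exact duplicates (same id and fitness), re-rank.
merge_leaders <- function(old, cur) {
  pool <- list(old$alpha, old$beta, old$delta, cur$alpha, cur$beta, cur$delta)
  key <- vapply(pool, function(a) paste(a$id, a$fitness), character(1))
  rank_leaders(pool[!duplicated(key)])
}
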