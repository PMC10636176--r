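#' Fitness configuration for the wrapper objective
#'
#' The wrapper objective trades classification error against subset size:
#' `fitness = alpha_w * error + beta_w * |S| / |D|`, minimized, where `|S|`
#' is the number of selected features and `|D|` the total. Defaults follow
#' the published protocol: `alpha_w = 0.9`, `beta_w = 1 - alpha_w = 0.1`,
#' KNN with `k = 5` neighbours, 10-fold stratified cross-validation.
#'
#' @param alpha_w Weight on the cross-validated classification error, in
#'   \[0, 1\].
#' @param k_neighbors Number of KNN neighbours.
#' @param n_folds Cross-validation fold count. When a class has fewer members
#'   than `n_folds`, the effective fold count drops to the minimum class size
#'   (with a warning).
#' @return An object of class `"fitness_config"`.
#' @export
fitness_config <- function(alpha_w = 0.9, k_neighbors = 5L, n_folds = 10L) {
  stopifnot(is.numeric(alpha_w), length(alpha_w) == 1L,
            alpha_w >= 0, alpha_w <= 1,
            k_neighbors >= 1, n_folds >= 2)
  structure(
    list(alpha_w = alpha_w, beta_w = 1 - alpha_w,
         k_neighbors = as.integer(k_neighbors),
         n_folds = as.integer(n_folds), distance = "euclidean"),
    class = "fitness_config"
  )
}

#' Euclidean distance between two vectors
#'
#' @param P,Q Numeric vectors of equal length.
#' @return The non-negative scalar `sqrt(sum((Q - P)^2))`.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(P, Q) {
  if (length(P) != length(Q)) {
    stop("P and Q must have equal length", call. = FALSE)
  }
  sqrt(sum((Q - P)^2))
}

#' K-nearest-neighbour prediction
#'
#' Majority label among the `k` training points nearest to the query in
#' Euclidean distance. Ties between classes break deterministically: the
#' tied class with the smallest summed neighbour distance wins, then the
#' lowest class index.
#'
#' @param train_x Numeric matrix of training samples (rows).
#' @param train_y Factor of training labels, one per row.
#' @param query Numeric vector (one sample) or matrix of query rows.
#' @param k Number of neighbours, `k <= nrow(train_x)`.
#' @return Factor of predicted labels (length = number of query rows).
#' @export
knn_predict <- function(train_x, train_y, query, k = 5L) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0L) stop("empty training set", call. = FALSE)
  if (!is.factor(train_y)) train_y <- factor(train_y)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(train_x)) {
    stop("query and training data must have the same number of columns",
         call. = FALSE)
  }
  if (k > nrow(train_x)) {
    stop("k cannot exceed the number of training samples", call. = FALSE)
  }
  D <- cross_dist(query, train_x)
  lev <- levels(train_y)
  yi <- as.integer(train_y)
  pred <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    o <- order(D[i, ])[seq_len(k)]
    cls <- yi[o]
    votes <- tabulate(cls, nbins = length(lev))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) sum(D[i, o[cls == cl]]), numeric(1))
      top <- top[order(sums, top)]
    }
    pred[i] <- top[1L]
  }
  factor(lev[pred], levels = lev)
}

# Pairwise Euclidean distance matrix, rows of A x rows of B.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` folds, preserving class
#' proportions: per class, indices are shuffled and folds filled cyclically.
#' If the smallest class has fewer members than `n_folds`, the fold count is
#' reduced to that size with a warning. Uses the current R random stream.
#'
#' @param y Factor of class labels.
#' @param n_folds Requested fold count.
#' @return Integer vector of fold ids in `1..n_folds_effective`.
#' @export
stratified_folds <- function(y, n_folds = 10L) {
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("cross-validation needs at least two classes", call. = FALSE)
  }
  min_class <- min(table(droplevels(y)))
  if (min_class < n_folds) {
    warning(sprintf(
      "smallest class has %d members; reducing fold count from %d to %d",
      min_class, n_folds, min_class), call. = FALSE)
    n_folds <- min_class
  }
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validated KNN error of a feature subset
#'
#' The wrapper error term: a stratified k-fold partition is drawn (or passed
#' in), and per fold a KNN classifier is fit on the remaining folds using
#' only the columns with a set mask bit. Features are min-max scaled to
#' \[0, 1\] using ranges learned on the training folds only. Returns the
#' misclassified fraction over all samples.
#'
#' @param x Numeric feature matrix (samples in rows).
#' @param y Factor of class labels.
#' @param mask Integer 0/1 vector, one per column; must have at least one
#'   bit set.
#' @param cfg A [fitness_config()].
#' @param folds Optional precomputed fold assignment (from
#'   [stratified_folds()]); if `NULL` one is drawn from the current random
#'   stream.
#' @return Error rate in \[0, 1\].
#' @export
cv_error <- function(x, y, mask, cfg = fitness_config(), folds = NULL) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  stopifnot(length(mask) == ncol(x))
  if (sum(mask) == 0L) stop("mask selects no features", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(y, cfg$n_folds)
  cols <- which(mask == 1L)
  xm <- x[, cols, drop = FALSE]
  wrong <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    tr_x <- xm[!te, , drop = FALSE]
    te_x <- xm[te, , drop = FALSE]
    rng_lo <- apply(tr_x, 2, min)
    rng_hi <- apply(tr_x, 2, max)
    span <- pmax(rng_hi - rng_lo, .Machine$double.eps)
    tr_s <- sweep(sweep(tr_x, 2, rng_lo), 2, span, "/")
    te_s <- sweep(sweep(te_x, 2, rng_lo), 2, span, "/")
    k <- min(cfg$k_neighbors, nrow(tr_s))
    pred <- knn_predict(tr_s, y[!te], te_s, k = k)
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

#' Wrapper fitness from error rate and subset size
#'
#' Combines the cross-validated error with the selected-subset fraction:
#' `total = alpha_w * error_rate + beta_w * n_selected / n_total`. Lower is
#' better; at the defaults a feature costs 0.1 / `n_total` fitness units, so
#' the search prefers the smallest subset among equally accurate ones.
#'
#' @param error_rate Classification error in \[0, 1\].
#' @param n_selected Number of selected features, `1 <= n_selected <=
#'   n_total`.
#' @param n_total Total number of features.
#' @param cfg A [fitness_config()].
#' @return A list with `total`, `error_rate` and `ratio` (= `n_selected /
#'   n_total`).
#' @export
#' @examples
#' selection_fitness(0.3, 5, 10)  # total = 0.9*0.3 + 0.1*0.5 = 0.32
selection_fitness <- function(error_rate, n_selected, n_total,
                              cfg = fitness_config()) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (n_selected < 1 || n_selected > n_total) {
    stop("n_selected must lie in [1, n_total]", call. = FALSE)
  }
  ratio <- n_selected / n_total
  list(total = cfg$alpha_w * error_rate + cfg$beta_w * ratio,
       error_rate = error_rate, ratio = ratio)
}
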