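#' Specification for a synthetic tabular dataset
#'
#' Describes a labelled feature table with known ground truth: informative
#' columns are class-conditional Gaussians with a total centroid separation
#' of `class_sep * noise_sd` split evenly across the informative columns
#' (each contributes a mean offset of `class_sep * noise_sd /
#' n_informative`), so each informative column alone is a distinctly weaker
#' classifier than the joint subspace and the full set is needed to realize
#' the declared effect size. Redundant columns are noisy linear combinations
#' of informative ones, and noise columns are independent of the label.
#'
#' @param n_samples Total rows, split as evenly as possible across classes.
#' @param n_informative,n_redundant,n_noise Column counts by role.
#' @param class_sep Centroid separation in noise-standard-deviation units.
#' @param noise_sd Within-class standard deviation.
#' @param n_classes Number of classes (default 2).
#' @param seed Integer seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_informative = 2L,
                           n_redundant = 0L, n_noise = 8L,
                           class_sep = 6, noise_sd = 1,
                           n_classes = 2L, seed = 1L) {
  stopifnot(n_samples >= n_classes * 2, n_informative >= 0, n_redundant >= 0,
            n_noise >= 0, class_sep > 0, noise_sd > 0, n_classes >= 2)
  if (n_informative + n_redundant + n_noise < 1) {
    stop("at least one column must be defined", call. = FALSE)
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant columns require at least one informative column",
         call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         n_noise = as.integer(n_noise),
         class_sep = class_sep, noise_sd = noise_sd,
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a labelled tabular dataset with known relevance structure
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (tibble: feature columns `inf*`, `red*`,
#'   `noise*` plus a `class` factor column) and `truth_mask` (named 0/1
#'   vector marking the columns that carry label signal: informative and
#'   redundant).
#' @export
#' @examples
#' d <- make_tabular(synthetic_spec(n_samples = 100, seed = 7))
#' table(d$data$class)
#' d$truth_mask
make_tabular <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_samples
  y <- factor(rep_len(paste0("c", seq_len(spec$n_classes)), n),
              levels = paste0("c", seq_len(spec$n_classes)))
  cols <- list()
  if (spec$n_informative > 0) {
    # total separation split evenly across informative columns
    sep <- spec$class_sep * spec$noise_sd / spec$n_informative
    for (j in seq_len(spec$n_informative)) {
      centers <- (as.integer(y) - 1) * sep
      cols[[paste0("inf", j)]] <- centers + stats::rnorm(n, 0, spec$noise_sd)
    }
  }
  if (spec$n_redundant > 0) {
    inf_mat <- do.call(cbind, cols[seq_len(spec$n_informative)])
    for (j in seq_len(spec$n_redundant)) {
      wts <- stats::rnorm(spec$n_informative)
      cols[[paste0("red", j)]] <-
        drop(inf_mat %*% wts) + stats::rnorm(n, 0, spec$noise_sd)
    }
  }
  if (spec$n_noise > 0) {
    for (j in seq_len(spec$n_noise)) {
      cols[[paste0("noise", j)]] <- stats::rnorm(n, 0, spec$noise_sd)
    }
  }
  data <- tibble::as_tibble(cols)
  truth <- as.integer(grepl("^(inf|red)", names(data)))
  names(truth) <- names(data)
  data$class <- y
  list(data = data, truth_mask = truth)
}

#' Generate a deep-feature-like table
#'
#' Emulates a table of penultimate-layer CNN activations: non-negative rows
#' (rectified Gaussian marginals) with class-dependent means on a random
#' informative subset of columns. Class labels are `healthy` / `diseased`
#' for two classes, `class1..K` otherwise.
#'
#' @param n_per_class Integer vector of per-class row counts (e.g.
#'   `c(159, 77)` mirroring the Lemon leaf dataset).
#' @param feat_dim Number of feature columns.
#' @param informative_frac Fraction of columns whose class means differ.
#' @param class_sep Mean shift between consecutive classes on informative
#'   columns, in within-class sd units (default 1, giving strong but
#'   imperfect separability comparable to deep features of visually distinct
#'   classes).
#' @param seed Integer seed.
#' @return A list of class `"feature_table"`: `features` (numeric matrix
#'   `sum(n_per_class) x feat_dim`), `labels` (factor), `image_ids`,
#'   `extractor_tag = "synthetic"`, and `informative` (column indices of the
#'   signal-carrying subset).
#' @export
make_feature_table <- function(n_per_class, feat_dim = 512L,
                               informative_frac = 0.05, class_sep = 1,
                               seed = 1L) {
  stopifnot(feat_dim >= 1, all(n_per_class >= 1),
            informative_frac >= 0, informative_frac <= 1)
  withr::local_seed(as.integer(seed))
  k <- length(n_per_class)
  labs <- if (k == 2) c("healthy", "diseased") else paste0("class", seq_len(k))
  y <- factor(rep(labs, times = n_per_class), levels = labs)
  n <- sum(n_per_class)
  n_inf <- round(informative_frac * feat_dim)
  informative <- sort(sample.int(feat_dim, n_inf))
  base_mean <- stats::runif(feat_dim, 0.5, 1.5)
  m <- matrix(stats::rnorm(n * feat_dim), n, feat_dim)
  m <- sweep(m, 2, base_mean, "+")
  if (n_inf > 0) {
    shift <- outer(as.integer(y) - 1, rep(class_sep, n_inf))
    m[, informative] <- m[, informative] + shift
  }
  m <- pmax(m, 0)
  colnames(m) <- sprintf("f%04d", seq_len(feat_dim))
  list(features = m, labels = y,
       image_ids = sprintf("img%04d", seq_len(n)),
       extractor_tag = "synthetic", informative = informative) |>
    structure(class = "feature_table")
}

#' Generate a toy leaf-image directory tree
#'
#' Writes a `root/<class>/*.png` tree of small synthetic leaf images:
#' smooth green-textured blobs, with dark elliptical lesions added at a
#' per-class Poisson rate. With the default rates (0 spots for healthy,
#' 5 expected spots for diseased) the classes are separable from simple
#' intensity statistics, which is what the pipeline's test extractor senses.
#'
#' @param n_per_class Images per class (scalar or length-2 vector for
#'   `healthy` / `diseased`).
#' @param dir Output root directory (created if missing).
#' @param size Image side length in pixels (>= 32).
#' @param lesion_density Expected lesion count per class, named or in
#'   `(healthy, diseased)` order.
#' @param seed Integer seed; pixel content is reproducible bit for bit.
#' @return The root directory path, invisibly.
#' @export
make_toy_images <- function(n_per_class, dir = tempfile("leaves"),
                            size = 64L, lesion_density = c(0, 5),
                            seed = 1L) {
  stopifnot(size >= 32)
  n_per_class <- rep_len(as.integer(n_per_class), 2L)
  lesion_density <- rep_len(as.numeric(lesion_density), 2L)
  withr::local_seed(as.integer(seed))
  classes <- c("healthy", "diseased")
  for (ci in seq_along(classes)) {
    cdir <- file.path(dir, classes[ci])
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_per_class[ci])) {
      img <- toy_leaf_image(size, lesion_density[ci])
      png::writePNG(img, file.path(cdir, sprintf("leaf%03d.png", i)))
    }
  }
  invisible(dir)
}

# One size x size x 3 array in [0,1]: green texture plus dark lesions.
toy_leaf_image <- function(size, rate) {
  coarse <- matrix(stats::runif(64, 0.3, 0.7), 8, 8)
  tex <- as.matrix(EBImage::resize(EBImage::Image(coarse), w = size,
                                   h = size))
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- 0.15 + 0.1 * tex
  img[, , 2] <- 0.35 + 0.45 * tex
  img[, , 3] <- 0.10 + 0.1 * tex
  n_spots <- stats::rpois(1, rate)
  if (n_spots > 0) {
    xs <- matrix(rep(seq_len(size), size), size, size)
    ys <- t(xs)
    for (s in seq_len(n_spots)) {
      cx <- stats::runif(1, size * 0.15, size * 0.85)
      cy <- stats::runif(1, size * 0.15, size * 0.85)
      rx <- stats::runif(1, size / 20, size / 8)
      ry <- stats::runif(1, size / 20, size / 8)
      inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- plane[inside] * 0.25 + c(0.12, 0.06, 0.02)[ch]
        img[, , ch] <- plane
      }
    }
  }
  pmin(pmax(img, 0), 1)
}
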