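#' Train/validation/test split specification
#'
#' @param train_frac,val_frac,test_frac Positive fractions summing to 1
#'   (default 0.70 / 0.15 / 0.15, stratified).
#' @param seed Integer seed for the split.
#' @return An object of class `"split_spec"`.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.15,
                       test_frac = 0.15, seed = 1L) {
  fr <- c(train_frac, val_frac, test_frac)
  stopifnot(all(fr > 0), abs(sum(fr) - 1) < 1e-8)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

# Stratified three-way partition; every class lands in every partition.
stratified_split <- function(y, split) {
  stopifnot(inherits(split, "split_spec"))
  withr::local_seed(split$seed)
  part <- character(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    n_tr <- max(1L, round(split$train_frac * n))
    n_va <- max(1L, round(split$val_frac * n))
    n_te <- n - n_tr - n_va
    if (n_te < 1L) stop("class '", cl, "' too small for a three-way split",
                        call. = FALSE)
    part[idx] <- rep(c("train", "val", "test"), c(n_tr, n_va, n_te))
  }
  part
}

#' Read and preprocess a class-folder image tree
#'
#' Reads `dir/<class>/*` raster images in deterministic lexicographic order,
#' resizes each to `target_size x target_size` and keeps values in \[0, 1\].
#' Unreadable files are skipped with a warning; a class folder with no
#' readable image is an error.
#'
#' @param image_dir Root directory with one subfolder per class.
#' @param target_size Output side length in pixels.
#' @return A list of class `"image_batch"`: `images` (list of
#'   `target_size x target_size x 3` arrays), `labels` (factor of folder
#'   names), `image_ids` (relative paths), `target_size`.
#' @export
preprocess_images <- function(image_dir, target_size = 64L) {
  classes <- sort(list.dirs(image_dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) {
    stop("no class subfolders found under ", image_dir, call. = FALSE)
  }
  images <- list(); labels <- character(); ids <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(image_dir, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    ok <- 0L
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        next
      }
      img <- EBImage::resize(img, w = target_size, h = target_size)
      a <- as_rgb_array(img, target_size)
      images[[length(images) + 1L]] <- a
      labels <- c(labels, cl)
      ids <- c(ids, file.path(cl, basename(f)))
      ok <- ok + 1L
    }
    if (ok == 0L) stop("class folder '", cl, "' holds no readable image",
                       call. = FALSE)
  }
  list(images = images, labels = factor(labels, levels = classes),
       image_ids = ids, target_size = as.integer(target_size)) |>
    structure(class = "image_batch")
}

as_rgb_array <- function(img, size) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(size, size, 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  pmin(pmax(a, 0), 1)
}

#' Deterministic image-statistics feature extractor
#'
#' The package's built-in extractor plug-in: a fixed projection of pixel
#' statistics. Each image contributes per-channel means and standard
#' deviations over an `n_blocks x n_blocks` spatial grid plus global channel
#' moments, for a declared width of `2 * (3 * n_blocks^2 + 3)` features.
#' Purely deterministic: the same image always maps to the same row. Any
#' `function(image_array) -> numeric` with a `"width"` attribute can stand
#' in for it, e.g. a wrapper around a pretrained CNN's penultimate layer.
#'
#' @param n_blocks Grid resolution per side (default 4).
#' @return An extractor function with attribute `width`.
#' @export
image_stats_extractor <- function(n_blocks = 4L) {
  n_blocks <- as.integer(n_blocks)
  f <- function(img) {
    size <- dim(img)[1]
    cuts <- cut(seq_len(size), n_blocks, labels = FALSE)
    out <- numeric(0)
    for (ch in 1:3) {
      plane <- img[, , ch]
      for (bx in seq_len(n_blocks)) {
        for (by in seq_len(n_blocks)) {
          blk <- plane[cuts == bx, cuts == by]
          out <- c(out, mean(blk), stats::sd(blk))
        }
      }
      out <- c(out, mean(plane), stats::sd(plane))
    }
    out
  }
  attr(f, "width") <- as.integer(2 * (3 * n_blocks^2 + 3))
  f
}

#' Extract a feature table from an image batch
#'
#' Applies an extractor plug-in row by row. Identical images yield identical
#' rows (the built-in extractor is deterministic).
#'
#' @param batch An `"image_batch"` from [preprocess_images()].
#' @param extractor An extractor function (default
#'   [image_stats_extractor()]).
#' @param tag Extractor tag recorded in the table.
#' @return A `"feature_table"` (see [make_feature_table()] for the shape).
#' @export
extract_features <- function(batch, extractor = image_stats_extractor(),
                             tag = "image_stats") {
  stopifnot(inherits(batch, "image_batch"), is.function(extractor))
  rows <- lapply(batch$images, extractor)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("extractor returned rows of differing width", call. = FALSE)
  }
  declared <- attr(extractor, "width")
  if (!is.null(declared) && widths[1] != declared) {
    stop("extractor output width ", widths[1],
         " does not match its declared width ", declared, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("f%04d", seq_len(ncol(m)))
  list(features = m, labels = batch$labels, image_ids = batch$image_ids,
       extractor_tag = tag, informative = NULL) |>
    structure(class = "feature_table")
}

svm_grid <- function() {
  expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10, 100),
              stringsAsFactors = FALSE)
}

#' Fit a maximum-margin classifier with validation-set tuning
#'
#' Fits support vector machines (via the libsvm backend in e1071) over a
#' small kernel/cost grid, picks the configuration with the highest
#' validation accuracy (ties: first in grid order), and refits nothing —
#' the winning model is trained on the training partition only. Multi-class
#' inputs use the backend's one-vs-one construction (`K (K - 1) / 2`
#' pairwise machines with majority vote).
#'
#' @param x_train,y_train Training features (matrix) and labels (factor).
#' @param x_val,y_val Validation partition used only to pick the grid cell.
#' @param grid Data frame of `kernel` / `cost` combinations.
#' @return A list of class `"svm_tuned"`: `model`, `kernel`, `cost`,
#'   `val_accuracy`, `classes`.
#' @export
train_svm <- function(x_train, y_train, x_val, y_val, grid = svm_grid()) {
  y_train <- droplevels(factor(y_train))
  if (nlevels(y_train) < 2L) {
    stop("training partition holds a single class", call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    m <- e1071::svm(x_train, y_train, kernel = grid$kernel[i],
                    cost = grid$cost[i], scale = FALSE)
    acc <- mean(stats::predict(m, x_val) == y_val)
    if (is.null(best) || acc > best$val_accuracy) {
      best <- list(model = m, kernel = grid$kernel[i], cost = grid$cost[i],
                   val_accuracy = acc, classes = levels(y_train))
    }
  }
  structure(best, class = "svm_tuned")
}

#' Continuous decision values of a tuned SVM
#'
#' Binary models only: returns `w . x - b` oriented so that larger values
#' favour the declared positive class.
#'
#' @param fit An `"svm_tuned"` object.
#' @param x Feature matrix.
#' @param positive Positive class label.
#' @return Numeric vector of decision values.
#' @export
svm_decision_values <- function(fit, x, positive) {
  stopifnot(inherits(fit, "svm_tuned"))
  p <- stats::predict(fit$model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  if (ncol(dv) != 1L) {
    stop("decision values are defined here for binary models only",
         call. = FALSE)
  }
  first <- strsplit(colnames(dv), "/")[[1]][1]
  if (identical(first, positive)) dv[, 1] else -dv[, 1]
}

#' Receiver-operating-characteristic points by threshold sweep
#'
#' Sweeps a threshold over the continuous decision values and records the
#' true- and false-positive rates, including the (0,0) and (1,1) endpoints.
#'
#' @param scores Numeric decision values (larger favours positive).
#' @param labels True labels.
#' @param positive Positive class label.
#' @return A tibble `threshold`, `fpr`, `tpr`, ordered along the curve.
#' @export
roc_points <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  purrr::map_dfr(thr, function(t) {
    pred_pos <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred_pos & !pos) / max(1, sum(!pos)),
                   tpr = sum(pred_pos & pos) / max(1, sum(pos)))
  })
}

#' Full select-then-classify pipeline
#'
#' The proposed-model pipeline on a feature table (or an image directory,
#' which is preprocessed and passed through the extractor first): a
#' stratified train/validation/test split is drawn; the MGWO wrapper selects
#' a feature mask on the training partition only; the SVM is trained on the
#' masked training partition and tuned on the validation partition; the
#' tuned model is scored exactly once on the test partition. Test rows never
#' participate in selection or tuning, and only masked columns are read at
#' test time.
#'
#' @param input A `"feature_table"` or a path to a class-folder image tree.
#' @param positive Positive class for the confusion matrix (default
#'   `"diseased"`).
#' @param split A [split_spec()] (its seed is derived from `seed` when left
#'   at default).
#' @param select Run MGWO selection (`TRUE`) or use `mask` / all features.
#' @param mask Optional fixed 0/1 mask (used when `select = FALSE`); `NULL`
#'   means all features.
#' @param n_agents,t_max,fitness,convention,representation Selection
#'   parameters, as in [select_features()].
#' @param extractor Extractor plug-in, used only when `input` is a
#'   directory.
#' @param seed Integer master seed (split and selection substreams derive
#'   from it).
#' @return An object of class `"pipeline_report"`: `metrics` (one-row
#'   tibble, percent), `confusion`, `roc` (threshold sweep tibble), `mask`,
#'   `selection` (the `"gwo_selection"` or `NULL`), `svm` (winning kernel /
#'   cost / validation accuracy), `partitions` (image ids by partition),
#'   `test_accuracy` (fraction), `seed`.
#' @export
run_pipeline <- function(input, positive = "diseased",
                         split = NULL, select = TRUE, mask = NULL,
                         n_agents = 5L, t_max = 20L,
                         fitness = fitness_config(),
                         convention = NULL,
                         representation = c("mask", "continuous"),
                         extractor = image_stats_extractor(),
                         seed = 1L) {
  seed <- as.integer(seed)
  if (is.character(input)) {
    input <- extract_features(preprocess_images(input), extractor)
  }
  stopifnot(inherits(input, "feature_table"))
  x <- input$features; y <- input$labels; ids <- input$image_ids
  if (is.null(split)) split <- split_spec(seed = substream(seed, 4L))
  part <- stratified_split(y, split)
  tr <- part == "train"; va <- part == "val"; te <- part == "test"

  selection <- NULL
  if (isTRUE(select)) {
    train_df <- tibble::as_tibble(as.data.frame(x[tr, , drop = FALSE]))
    train_df$class <- y[tr]
    selection <- select_features(train_df, class_col = "class",
                                 algorithm = "mgwo", n_agents = n_agents,
                                 t_max = t_max, fitness = fitness,
                                 convention = convention,
                                 representation = match.arg(representation),
                                 seed = substream(seed, 5L))
    mask <- unname(selection$best_mask)
  } else if (is.null(mask)) {
    mask <- rep(1L, ncol(x))
  }
  stopifnot(length(mask) == ncol(x), sum(mask) >= 1)
  cols <- which(mask == 1L)

  fit <- train_svm(x[tr, cols, drop = FALSE], y[tr],
                   x[va, cols, drop = FALSE], y[va])
  x_te <- x[te, cols, drop = FALSE]
  pred <- stats::predict(fit$model, x_te)
  cm <- confusion_matrix(as.character(y[te]), as.character(pred), positive)
  metrics <- derive_metrics(cm)
  roc <- if (nlevels(droplevels(y)) == 2L) {
    roc_points(svm_decision_values(fit, x_te, positive), y[te], positive)
  }

  structure(
    list(metrics = metrics, confusion = cm, roc = roc,
         mask = mask, selection = selection,
         svm = list(kernel = fit$kernel, cost = fit$cost,
                    val_accuracy = fit$val_accuracy),
         partitions = list(train = ids[tr], val = ids[va], test = ids[te]),
         test_accuracy = mean(pred == y[te]), positive = positive,
         seed = seed),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, %d/%d features, svm %s (cost %g)\n",
              x$seed, sum(x$mask), length(x$mask), x$svm$kernel, x$svm$cost))
  print(x$metrics)
  invisible(x)
}

#' Tidy methods for pipeline reports
#'
#' @param x A `"pipeline_report"`.
#' @param ... Unused.
#' @return `tidy()`: the per-metric long tibble (`metric`, `value` percent).
#'   `glance()`: one row with accuracy, F1, selected-feature count, the
#'   winning SVM configuration and the seed.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.pipeline_report
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(accuracy = x$metrics$accuracy, f1 = x$metrics$f1,
                 n_selected = sum(x$mask), n_features = length(x$mask),
                 kernel = x$svm$kernel, cost = x$svm$cost,
                 val_accuracy = 100 * x$svm$val_accuracy, seed = x$seed)
}

#' ROC curve of a pipeline report
#'
#' @param object A `"pipeline_report"` with a binary outcome.
#' @param ... Unused.
#' @return A ggplot of the test-set ROC curve.
#' @method autoplot pipeline_report
#' @export
autoplot.pipeline_report <- function(object, ...) {
  stopifnot(!is.null(object$roc))
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Test-set ROC") +
    ggplot2::theme_minimal()
}
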