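#' Published leaf-disease benchmark metrics
#'
#' Reference classification results for four models (a pretrained AlexNet
#' classifier, GoogleNet, an SVM on deep features without selection, and the
#' proposed AlexNet-features + MGWO-selection + SVM model) on ten plant
#' leaf-disease datasets (healthy vs diseased; Mango, Arjun, Alstonia,
#' Guava, Jamun, Jatropha, Sukh Chain, Pomegranate, Lemon and Chinar,
#' coded P0--P11). All values are percentages as published. These serve as
#' inputs to the reporting utilities: macro averages recompute from the
#' accuracy column ([macro_summary()]) and every F1 cell is consistent with
#' its precision and sensitivity cells through [f1_score()].
#'
#' @return A tibble with columns `model`, `dataset`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `accuracy` (40 rows).
#' @export
#' @examples
#' macro_summary(leaf_benchmark_metrics())
leaf_benchmark_metrics <- function() {
  ds <- c("P0", "P1", "P2", "P3", "P5", "P6", "P7", "P9", "P10", "P11")
  alexnet <- rbind(
    c(100,   90.6,  94.2,  97.01, 96.3),
    c(92.3,  95,    96,    94.11, 93.5),
    c(97.7,  45.7,  68.9,  80.81, 74.4),
    c(100,   100,   100,   100,   100),
    c(93.8,  68.5,  78.2,  85.29, 82.4),
    c(82.3,  93.3,  93.3,  87.46, 87.5),
    c(100,   100,   100,   100,   100),
    c(74.5,  56.7,  61.2,  67.2,  65.2),
    c(66.7,  70,    52.6,  58.82, 68.9),
    c(84,    90,    91.3,  87.5,  86.7))
  googlenet <- rbind(
    c(95.45, 97.08, 97.22, 96.33, 96.24),
    c(98.1,  82.5,  87.9,  92.72, 91.3),
    c(90.7,  82.9,  86.7,  88.65, 87.2),
    c(100,   96.7,  92.6,  96.16, 97.6),
    c(81.3,  78.9,  76.5,  78.83, 80),
    c(85,    84,    81,    82.95, 84.4),
    c(100,   98.3,  98.2,  99.09, 99.1),
    c(89.1,  73.3,  75.4,  81.68, 80.9),
    c(60,    86.7,  69.2,  64.27, 77.8),
    c(80,    90,    90.9,  85.1,  84.4))
  svm <- rbind(
    c(94.74, 96.15, 96.43, 95.58, 95.41),
    c(92.11, 93.75, 94.59, 93.33, 92.86),
    c(86.84, 83.33, 84.62, 85.71, 85.14),
    c(98.04, 98.77, 99.01, 98.52, 98.36),
    c(80.68, 79.07, 79.78, 80.23, 79.89),
    c(82.46, 82.57, 83.19, 82.82, 82.51),
    c(96.91, 97.83, 97.92, 97.41, 97.35),
    c(80.34, 78.26, 78.99, 79.66, 79.31),
    c(77.39, 76.19, 78.07, 77.73, 76.82),
    c(82.91, 82.57, 83.62, 83.26, 82.74))
  proposed <- rbind(
    c(97.2,  100,   100,   98.6,  98.8),
    c(94.2,  97.5,  98,    96.06, 95.7),
    c(88.7,  84,    86.2,  87.43, 86.5),
    c(100,   100,   100,   100,   100),
    c(89.5,  81.5,  85,    87.19, 85.8),
    c(95.1,  94.1,  95.1,  95.1,  94.7),
    c(100,   100,   100,   100,   100),
    c(81,    100,   100,   89.5,  91),
    c(94.4,  93.8,  94.4,  94.4,  94.1),
    c(87.9,  96.4,  96.7,  92.09, 91.8))
  blocks <- list(alexnet = alexnet, googlenet = googlenet, svm = svm,
                 proposed = proposed)
  purrr::imap_dfr(blocks, function(m, name) {
    tibble::tibble(model = name, dataset = ds,
                   sensitivity = m[, 1], specificity = m[, 2],
                   precision = m[, 3], f1 = m[, 4], accuracy = m[, 5])
  })
}

#' Tabular feature-selection benchmark registry
#'
#' The fifteen standard tabular datasets used to benchmark the wrapper
#' selector, with their published instance/attribute/class counts. The
#' datasets themselves are not shipped (they are external UCI-style
#' downloads); the registry documents names and dimensions so run
#' configurations can refer to them, and the synthetic generator
#' ([make_tabular()]) stands in for them in tests.
#'
#' Note one naming discrepancy in the source tables: the dataset list names
#' `WineEW` while the result tables name `spectEW` (22 attributes); both
#' entries are kept, `spectEW` with its conventional instance/class counts.
#'
#' @return A tibble: `dataset`, `n_instances`, `n_attributes`, `n_classes`.
#' @export
fs_benchmark_registry <- function() {
  tibble::tribble(
    ~dataset,        ~n_instances, ~n_attributes, ~n_classes,
    "Breast cancer", 699L,  9L,  2L,
    "Climate",       540L, 20L,  2L,
    "Diabetic",     1151L, 19L,  2L,
    "Ionosphere",    351L, 34L,  2L,
    "kc1",          2110L, 21L,  2L,
    "Lung Cancer",   226L, 23L,  2L,
    "lymphography",  148L, 18L,  4L,
    "pc1",          1109L, 21L,  2L,
    "Stock",         950L,  9L,  2L,
    "Segment",      2310L, 19L,  7L,
    "WineEW",        178L, 13L,  3L,
    "spectEW",       267L, 22L,  2L,
    "Tic-tac-toe",   958L,  9L,  2L,
    "Vote",          300L, 16L,  2L,
    "WDBC",          569L, 30L,  2L,
    "Zoo",           101L, 16L,  7L
  )
}
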