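#' Read a labelled feature table from delimited text
#'
#' Comma-separated, UTF-8, `.` decimal, header row, one class-label column.
#' Every other column must parse as numeric; the first offending cell is
#' reported by row and column.
#'
#' @param path File path.
#' @param class_col Name of the label column (default `"class"`).
#' @return A tibble with numeric feature columns and a factor `class_col`,
#'   row order preserved.
#' @export
read_tabular <- function(path, class_col = "class") {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!class_col %in% names(raw)) {
    stop(sprintf("label column '%s' missing from %s", class_col, path),
         call. = FALSE)
  }
  for (nm in setdiff(names(raw), class_col)) {
    v <- raw[[nm]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) | is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1], nm), call. = FALSE)
    }
    raw[[nm]] <- parsed
  }
  raw[[class_col]] <- factor(raw[[class_col]])
  tibble::as_tibble(raw)
}

#' Read a feature table with labels from delimited text
#'
#' Like [read_tabular()] but returns the pipeline's `"feature_table"`
#' container (numeric matrix + label factor).
#'
#' @inheritParams read_tabular
#' @return A `"feature_table"`.
#' @export
read_feature_table <- function(path, class_col = "class") {
  tbl <- read_tabular(path, class_col)
  y <- tbl[[class_col]]
  m <- as.matrix(tbl[setdiff(names(tbl), class_col)])
  list(features = m, labels = y,
       image_ids = sprintf("row%04d", seq_len(nrow(m))),
       extractor_tag = "file", informative = NULL) |>
    structure(class = "feature_table")
}

#' Write a labelled feature table to CSV
#'
#' @param data Data frame with a class column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration with published defaults
#'
#' A flat key-value configuration for selection runs. Defaults follow the
#' published protocol: 5 search agents, 20 iterations, 20 independent runs,
#' error weight 0.9 (subset weight 0.1), 5 KNN neighbours, 10 CV folds.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the default keys.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(agents = 5L, iterations = 20L, runs = 20L,
                   alpha = 0.9, k = 5L, folds = 10L,
                   algorithm = "mgwo", convention = "as_printed",
                   class_col = "class", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Read / write a key=value run-configuration file
#'
#' @param path File of `key = value` lines (`#` comments allowed).
#' @return [read_run_config()]: a `"run_config"`. [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed configuration line: ", lines[bad][1],
                     call. = FALSE)
  vals <- lapply(kv, function(p) utils::type.convert(p[2], as.is = TRUE))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A `"run_config"`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, as.character, character(1))), path)
  invisible(path)
}

config_hash <- function(x) digest::digest(unclass(x), algo = "xxhash32")

#' Write result objects with provenance
#'
#' Serializes selection results, benchmark rows and pipeline reports to
#' `out_dir`: JSON for every object (with the seed and a configuration hash
#' embedded) and benchmark/metrics CSVs shaped like the published tables.
#'
#' @param objects Named list of `"gwo_selection"`, benchmark tibbles (from
#'   [run_experiment()]) or `"pipeline_report"` objects.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(objects, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  written <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "gwo_selection")) {
      payload <- c(glance(obj),
                   list(mask = unname(obj$best_mask),
                        features = names(obj$best_mask),
                        convergence = obj$convergence,
                        config_hash = config_hash(obj[c("engine", "fitness",
                                                        "convention")]),
                        timestamp = format(Sys.time(), tz = "UTC")))
      f <- file.path(out_dir, paste0(nm, "_selection.json"))
      jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    } else if (inherits(obj, "pipeline_report")) {
      payload <- list(metrics = obj$metrics,
                      confusion = obj$confusion[c("TP", "TN", "FP", "FN")],
                      svm = obj$svm, n_selected = sum(obj$mask),
                      seed = obj$seed,
                      config_hash = config_hash(obj[c("mask", "positive")]),
                      timestamp = format(Sys.time(), tz = "UTC"))
      f <- file.path(out_dir, paste0(nm, "_report.json"))
      jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    } else if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      flat <- obj[setdiff(names(obj), "runs")]
      utils::write.csv(flat, f, row.names = FALSE)
      written <- c(written, f)
    } else {
      stop("unsupported result object: ", nm, call. = FALSE)
    }
  }
  invisible(written)
}
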