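# File formats, configuration, report assembly, and the end-to-end pipeline
# behind the command-line entry points.

#' Write a signal to headered delimited text
#'
#' One amplitude per line, preceded by `# ts=`, `# t0=`, `# label=` header
#' comments. Refuses non-finite amplitudes.
#'
#' @param signal a [pa_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "pa_signal"))
  if (!all(is.finite(signal$samples))) stop("write_signal: non-finite amplitudes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ts=%.17g", signal$ts),
               sprintf("# t0=%.17g", signal$t0),
               sprintf("# label=%s", signal$label),
               sprintf("%.17g", signal$samples)), con)
  invisible(path)
}

#' Read a signal from headered delimited text
#'
#' @param path file written by [write_signal()] (or any text file with a
#'   `# ts=` header and one amplitude per line).
#' @return a [pa_signal()].
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("read_signal: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("read_signal: empty file: ", path)
  hdr <- grepl("^\\s*#", lines)
  ts <- t0 <- NA_real_
  label <- "unlabeled"
  for (h in lines[hdr]) {
    kv <- sub("^\\s*#\\s*", "", h)
    if (grepl("^ts=", kv)) ts <- as.numeric(sub("^ts=", "", kv))
    if (grepl("^t0=", kv)) t0 <- as.numeric(sub("^t0=", "", kv))
    if (grepl("^label=", kv)) label <- sub("^label=", "", kv)
  }
  if (is.na(ts)) stop("read_signal: missing '# ts=' header in ", path)
  if (is.na(t0)) t0 <- 0
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("read_signal: no amplitude lines in ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[body_idx])))
  if (anyNA(vals)) {
    bad <- body_idx[which(is.na(vals))[1]]
    stop(sprintf("read_signal: non-numeric amplitude at line %d of %s", bad, path))
  }
  if (!all(is.finite(vals))) stop("read_signal: non-finite amplitude in ", path)
  pa_signal(vals, ts = ts, t0 = t0, label = label)
}

#' Write a dataset directory (one file per signal + manifest)
#'
#' @param signals list of [pa_signal()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(signals, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("signal_%03d.txt", seq_along(signals))
  for (k in seq_along(signals)) write_signal(signals[[k]], file.path(dir, fn[k]))
  manifest <- data.frame(filename = fn,
                         label = vapply(signals, function(s) s$label, character(1)),
                         stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of [pa_signal()].
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("read_dataset: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(k) {
    s <- read_signal(file.path(dir, manifest$filename[k]))
    s$label <- manifest$label[k]
    s
  })
}

#' Read a run configuration from JSON
#'
#' Recognized top-level keys: `ts`, `duration`, `t0`, `snr_db`, `seed`,
#' `classes` (array of objects with the [pa_class_spec()] fields), plus
#' optional `i`, `max_order`, `order_override`, `decimate_to`, `fd_band`,
#' `split`, `n_test_per_class`. Missing keys fall back to package defaults.
#'
#' @param path JSON file.
#' @return list with `config` (a [pa_sim_config()]) and `options`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  classes <- default_class_table()
  if (!is.null(raw$classes)) {
    df <- as.data.frame(raw$classes)
    classes <- lapply(seq_len(nrow(df)), function(k) do.call(pa_class_spec, as.list(df[k, ])))
  }
  grab <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  config <- pa_sim_config(
    classes = classes,
    ts = grab("ts", 1e-8),
    duration = grab("duration", 1.2e-6),
    t0 = grab("t0", 6.5e-6),
    snr_db = grab("snr_db", 30),
    seed = grab("seed", 1L))
  options <- list(
    i = grab("i", 20L),
    max_order = grab("max_order", 10L),
    order_override = raw$order_override,
    decimate_to = grab("decimate_to", 1e8),
    fd_band = grab("fd_band", c(1e6, 2e7)),
    split = grab("split", "holdout"),
    n_test_per_class = grab("n_test_per_class", 4L))
  list(config = config, options = options)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write the benchmark report to disk
#'
#' Emits an accuracy table, per-family confusion matrices, the per-parameter
#' group-comparison (ANOVA + Bonferroni) table for the SS features, the
#' LD1/LD2 score and ellipse tables, a per-class NRMSE table, and a
#' machine-readable `summary.json` embedding the seed and a configuration
#' hash.
#'
#' @param bench a [run_benchmark()] result.
#' @param dir output directory (created if absent).
#' @param group_comparisons optional list of [anova_bonferroni()] results.
#' @param nrmse_by_class optional data frame (`label`, `nrmse`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bench, dir, group_comparisons = NULL,
                         nrmse_by_class = NULL) {
  stopifnot(inherits(bench, "pa_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fams <- names(bench$families)
  acc <- data.frame(family = fams,
                    accuracy = vapply(fams, function(f) bench$families[[f]]$accuracy, numeric(1)),
                    n_test = vapply(fams, function(f) bench$families[[f]]$report$n, numeric(1)),
                    n_excluded = vapply(fams, function(f) bench$families[[f]]$n_excluded, numeric(1)))
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  for (f in fams) {
    utils::write.csv(as.data.frame(bench$families[[f]]$report$confusion),
                     file.path(dir, sprintf("confusion_%s.csv", f)), row.names = FALSE)
    sc <- bench$families[[f]]$scores
    utils::write.csv(data.frame(label = bench$families[[f]]$score_labels, sc),
                     file.path(dir, sprintf("ld_scores_%s.csv", f)), row.names = FALSE)
    ell <- bench$families[[f]]$ellipses
    if (length(ell)) {
      edf <- do.call(rbind, lapply(names(ell), function(cl) {
        e <- ell[[cl]]
        data.frame(label = cl, center_x = e$center[1], center_y = e$center[2],
                   semi_axis_1 = e$semi_axes[1], semi_axis_2 = e$semi_axes[2],
                   rotation_rad = e$rotation, level = e$level)
      }))
      utils::write.csv(edf, file.path(dir, sprintf("ellipses_%s.csv", f)),
                       row.names = FALSE)
    }
  }
  if (!is.null(group_comparisons)) {
    gdf <- do.call(rbind, lapply(group_comparisons, function(gc) {
      cbind(parameter = gc$parameter_name, anova_F = gc$anova_F,
            anova_p = gc$anova_p, gc$pairwise)
    }))
    utils::write.csv(gdf, file.path(dir, "group_comparisons.csv"), row.names = FALSE)
  }
  if (!is.null(nrmse_by_class)) {
    utils::write.csv(nrmse_by_class, file.path(dir, "nrmse_by_class.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    seed = bench$seed,
    split = bench$split,
    config_hash = config_hash(bench$config),
    n_train = bench$n_train,
    n_test = bench$n_test,
    accuracy = stats::setNames(as.list(acc$accuracy), acc$family))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the whole pipeline end to end
#'
#' Simulate, identify every trace, extract all four feature families,
#' compute per-parameter group statistics and per-class NRMSE on the SS fits,
#' classify, and write the report. Per-sample failures are logged and
#' excluded, never imputed; if more than 20% of samples fail the run errors
#' out (nonzero exit under `Rscript`).
#'
#' @param config a [pa_sim_config()].
#' @param out_dir report directory.
#' @param families feature families to benchmark.
#' @param split `"holdout"` or `"resubstitution"`.
#' @param seed RNG seed (default: `config$seed`).
#' @return invisibly, a list with the benchmark, group comparisons and the
#'   NRMSE table.
#' @export
end_to_end <- function(config = pa_sim_config(), out_dir,
                       families = c("TD", "FD", "ARMA", "SS"),
                       split = "holdout", seed = config$seed) {
  bench <- run_benchmark(config, families = families, split = split, seed = seed)
  if (length(bench$families) == 0L) stop("end_to_end: all feature families failed")
  gcs <- NULL
  nrmse_tab <- NULL
  if ("SS" %in% names(bench$families)) {
    fm <- bench$families$SS$features_train
    n_expected <- bench$n_train
    if (nrow(fm$x) < 0.8 * n_expected) {
      stop(sprintf("end_to_end: %d of %d samples failed SS extraction (> 20%%)",
                   n_expected - nrow(fm$x), n_expected))
    }
    gcs <- lapply(colnames(fm$x), function(param) {
      anova_bonferroni(split(fm$x[, param], fm$labels), parameter_name = param)
    })
    # per-class mean reconstruction NRMSE (Table-2-style)
    cfg_train <- config
    cfg_train$seed <- as.integer(seed)
    train <- simulate_dataset(cfg_train)
    fit_nrmse <- vapply(train, function(s) {
      tryCatch(identify_ss(s, order_override = 2L)$nrmse, error = function(e) NA_real_)
    }, numeric(1))
    labs <- vapply(train, function(s) s$label, character(1))
    nrmse_tab <- do.call(rbind, lapply(sort(unique(labs)), function(cl) {
      data.frame(label = cl, nrmse = mean(fit_nrmse[labs == cl], na.rm = TRUE))
    }))
  }
  write_report(bench, out_dir, group_comparisons = gcs, nrmse_by_class = nrmse_tab)
  invisible(list(benchmark = bench, group_comparisons = gcs,
                 nrmse_by_class = nrmse_tab))
}
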