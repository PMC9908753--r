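# package-level state for the logger
.braindgcnn_env <- new.env(parent = emptyenv())
.braindgcnn_env$log_file <- NULL
.braindgcnn_env$verbosity <- "INFO"

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Structured logging
#'
#' Writes a timestamped `LEVEL stage: message` line to the console and, when
#' configured via `set_log_file()`, appends it to the run log. Messages below
#' the configured verbosity are suppressed on the console but always written
#' to the file, so the log replays the full stage sequence of a run.
#'
#' @param level `"DEBUG"`, `"INFO"`, `"WARN"` or `"ERROR"`.
#' @param stage Short stage tag (e.g. `"fc"`, `"train"`).
#' @param msg Message text.
#' @export
log_event <- function(level, stage, msg) {
  level <- match.arg(level, names(.log_levels))
  line <- sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), level, stage, msg)
  if (!is.null(.braindgcnn_env$log_file)) {
    cat(line, "\n", file = .braindgcnn_env$log_file, append = TRUE, sep = "")
  }
  if (.log_levels[level] >= .log_levels[.braindgcnn_env$verbosity]) {
    message(line)
  }
  invisible(NULL)
}

#' @rdname log_event
#' @param path Log file path (`NULL` disables file logging).
#' @param verbosity Minimum level echoed to the console.
#' @export
set_log_file <- function(path = NULL, verbosity = "INFO") {
  .braindgcnn_env$log_file <- path
  .braindgcnn_env$verbosity <- match.arg(verbosity, names(.log_levels))
  invisible(NULL)
}

#' End-to-end pipeline configuration
#'
#' @param manifest Path to a cohort manifest CSV, or `NULL` to generate the
#'   synthetic cohort described by `synthetic_spec`.
#' @param output_dir Directory receiving all result files.
#' @param tau Binarization threshold (default 0.3, the paper-style working
#'   point).
#' @param thresholds Thresholds swept in the connectivity report.
#' @param dgcnn A [dgcnn_config()].
#' @param protocol Evaluation protocol: `"holdout"` (90/10), `"kfold"`, or
#'   `"loso"` (leave one site out).
#' @param k_folds Folds for `"kfold"`.
#' @param train_fraction Training fraction for `"holdout"`.
#' @param synthetic_spec A [synthetic_cohort_spec()] used when `manifest` is
#'   `NULL`.
#' @param split_seed Seed for the holdout/fold assignment.
#' @param absolute Threshold absolute correlations.
#' @param verbosity Console log level.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, output_dir = "results",
                            tau = 0.3, thresholds = c(0.2, 0.3, 0.4),
                            dgcnn = dgcnn_config(),
                            protocol = c("holdout", "kfold", "loso"),
                            k_folds = 10L, train_fraction = 0.9,
                            synthetic_spec = synthetic_cohort_spec(),
                            split_seed = dgcnn$seed, absolute = FALSE,
                            verbosity = "INFO") {
  protocol <- match.arg(protocol)
  stopifnot(tau > 0, tau < 1, all(thresholds > 0 & thresholds < 1))
  structure(list(manifest = manifest, output_dir = output_dir, tau = tau,
                 thresholds = thresholds, dgcnn = dgcnn, protocol = protocol,
                 k_folds = as.integer(k_folds),
                 train_fraction = train_fraction,
                 synthetic_spec = synthetic_spec,
                 split_seed = as.integer(split_seed), absolute = absolute,
                 verbosity = verbosity),
            class = "pipeline_config")
}

write_metrics_csv <- function(df, path) {
  df_fmt <- df
  for (nm in names(df_fmt)) {
    if (is.numeric(df_fmt[[nm]])) df_fmt[[nm]] <- sprintf("%.6f", df_fmt[[nm]])
  }
  utils::write.csv(df_fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Read (or simulate) the cohort, compute per-subject FC matrices, sweep the
#' connectivity report over the configured thresholds, build binary graphs
#' at the working threshold, train and evaluate the DGCNN under the chosen
#' protocol, and write every artifact to `output_dir`:
#' `connectivity.csv`, `metrics.csv`, `history.csv` (holdout protocol),
#' `roc.csv`, `checkpoint.json` (holdout), `run_manifest.json` (config +
#' seeds; timestamp-free so reruns are bit-identical) and `run.log`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`connectivity`,
#'   `result`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set_log_file(file.path(config$output_dir, "run.log"),
               verbosity = config$verbosity)
  on.exit(set_log_file(NULL), add = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    log_event("INFO", name, "start")
    r <- tryCatch(expr, error = function(e) {
      log_event("ERROR", name, conditionMessage(e))
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
    log_event("INFO", name, "done")
    r
  }
  log_event("INFO", "pipeline", "start")

  cohort <- stage("read", {
    if (is.null(config$manifest)) {
      generate_cohort(config$synthetic_spec)
    } else {
      read_cohort(config$manifest)
    }
  })
  fcs <- stage("fc", lapply(cohort, pearson_fc))
  conn <- stage("connectivity", {
    tab <- connectivity_table(fcs, config$thresholds,
                              absolute = config$absolute)
    paths$connectivity <- file.path(config$output_dir, "connectivity.csv")
    write_metrics_csv(tab, paths$connectivity)
    tab
  })
  graphs <- stage("binarize", {
    lapply(fcs, function(fc) {
      build_graph(fc, threshold_binarize(fc, config$tau,
                                         absolute = config$absolute))
    })
  })

  result <- stage("evaluate", {
    labels <- vapply(graphs, function(g) g$label, character(1))
    if (config$protocol == "holdout") {
      sp <- holdout_split(labels, config$train_fraction, config$split_seed)
      model <- train_dgcnn(graphs[sp$train], graphs[sp$test], config$dgcnn)
      preds <- stats::predict(model, graphs[sp$test])
      rep_ <- fold_metrics(preds, labels[sp$test])
      paths$history <- file.path(config$output_dir, "history.csv")
      write_metrics_csv(model$history, paths$history)
      paths$checkpoint <- file.path(config$output_dir, "checkpoint.json")
      save_checkpoint(model, paths$checkpoint)
      roc <- roc_curve(preds$p_MDD, as.numeric(labels[sp$test] == "MDD"))
      paths$roc <- file.path(config$output_dir, "roc.csv")
      write_metrics_csv(roc, paths$roc)
      mdf <- data.frame(unit = "holdout", ACC = rep_$ACC, SEN = rep_$SEN,
                        SPE = rep_$SPE, PRE = rep_$PRE, F1 = rep_$F1,
                        AUC = rep_$AUC)
      list(report = rep_, metrics_df = mdf, model = model)
    } else if (config$protocol == "kfold") {
      cv <- kfold_cv(graphs, config$k_folds, config$dgcnn,
                     seed = config$split_seed)
      roc <- roc_curve(cv$predictions$p_MDD,
                       as.numeric(cv$predictions$truth == "MDD"))
      paths$roc <- file.path(config$output_dir, "roc.csv")
      write_metrics_csv(roc, paths$roc)
      list(report = cv$aggregate, metrics_df = as.data.frame(cv), cv = cv)
    } else {
      cv <- leave_one_site_out(graphs, config$dgcnn)
      list(report = cv$aggregate, metrics_df = as.data.frame(cv), cv = cv)
    }
  })
  paths$metrics <- file.path(config$output_dir, "metrics.csv")
  write_metrics_csv(result$metrics_df, paths$metrics)

  paths$run_manifest <- file.path(config$output_dir, "run_manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("braindgcnn")),
    config = list(
      manifest = config$manifest, tau = config$tau,
      thresholds = config$thresholds, protocol = config$protocol,
      k_folds = config$k_folds, train_fraction = config$train_fraction,
      absolute = config$absolute, split_seed = config$split_seed,
      dgcnn = unclass(config$dgcnn),
      synthetic_spec = if (is.null(config$manifest))
        unclass(config$synthetic_spec)),
    n_subjects = length(cohort))
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log_event("INFO", "pipeline", "end")
  invisible(list(connectivity = conn, result = result, paths = paths))
}
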