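#' Write a cohort to a manifest + per-subject TSV layout
#'
#' One TSV per subject (`n_rois` rows x `T` columns, no header, full
#' precision) plus `manifest.csv` with columns `subject_id`, `path`, `label`,
#' `site_id`. Paths in the manifest are relative to its directory, so the
#' layout is relocatable.
#'
#' @param cohort List of `roi_ts` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(ts) {
    fname <- paste0(ts$subject_id, ".tsv")
    utils::write.table(
      format(ts$signals, digits = 17, trim = TRUE, scientific = TRUE),
      file.path(dir, fname),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    data.frame(subject_id = ts$subject_id, path = fname, label = ts$label,
               site_id = ts$site_id)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' Loads and validates every subject listed in a manifest CSV (columns
#' `subject_id`, `path`, `label`, `site_id`; labels case-insensitive;
#' relative paths resolved against the manifest's directory). Files are read
#' as ROI-by-time matrices; if a matrix has more rows than columns it is
#' transposed only when an `n_rois` hint makes the orientation unambiguous.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param n_rois Optional expected ROI count used to auto-detect orientation;
#'   an ambiguous file (neither dimension matches) is an error.
#' @return List of `roi_ts` objects in manifest order.
#' @export
read_cohort <- function(manifest_path, n_rois = NULL) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label", "site_id")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    path <- if (file.exists(row$path)) row$path else file.path(base, row$path)
    if (!file.exists(path)) {
      stop("signal file missing for subject ", row$subject_id, ": ",
           row$path, call. = FALSE)
    }
    sig <- tryCatch(
      as.matrix(utils::read.table(path, sep = "\t", header = FALSE)),
      error = function(e) stop("malformed signal file for subject ",
                               row$subject_id, ": ", conditionMessage(e),
                               call. = FALSE))
    dimnames(sig) <- NULL
    if (!is.null(n_rois) && nrow(sig) != n_rois) {
      if (ncol(sig) == n_rois) {
        sig <- t(sig)
      } else {
        stop("subject ", row$subject_id, ": neither dimension matches n_rois=",
             n_rois, call. = FALSE)
      }
    }
    tryCatch(
      roi_time_series(sig, row$subject_id, row$label, row$site_id),
      error = function(e) stop("subject ", row$subject_id, ": ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' Write an FC or adjacency matrix as square CSV
#'
#' @param m Matrix (`fc_matrix`, `binary_adjacency`, or plain).
#' @param path Output CSV path (no row/col names; 0-based node order is
#'   implicit in the row/column positions).
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an undirected edge list
#'
#' TSV with columns `node_i`, `node_j`, `weight`, 0-based node indices,
#' one row per undirected edge (i < j). For a binary adjacency the weight
#' column is 1; pass `weights` (e.g. the FC matrix) to attach correlation
#' weights.
#'
#' @param adj `binary_adjacency`.
#' @param path Output TSV path.
#' @param weights Optional square matrix of edge weights.
#' @export
write_edge_list <- function(adj, path, weights = NULL) {
  a <- unclass(adj)
  ij <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(ij)) else unclass(weights)[ij]
  df <- data.frame(node_i = ij[, 1] - 1L, node_j = ij[, 2] - 1L, weight = w)
  df <- df[order(df$node_i, df$node_j), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive of every parameter array (with dimensions), the
#' configuration, and the training history — plain text, so checkpoints
#' survive any transport that handles text.
#'
#' @param model A `dgcnn_model`.
#' @param path Output `.json` path.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }),
    history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path Path to a checkpoint written by [save_checkpoint()].
#' @return `load_checkpoint()` returns the reconstructed `dgcnn_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(dgcnn_config, payload$config[setdiff(names(payload$config),
                                                      character(0))])
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(list(params = params, config = cfg,
                 history = as.data.frame(payload$history)),
            class = "dgcnn_model")
}
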