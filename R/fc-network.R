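#' ROI time-series container
#'
#' Bundles one subject's ROI-averaged resting-state signal matrix with its
#' diagnostic label and acquisition-site identifier. Rows are regions of
#' interest (ROIs), columns are time points.
#'
#' @param signals Numeric matrix, `n_rois x T`. Every row must have nonzero
#'   variance (a constant signal makes the Pearson correlation undefined and
#'   almost always indicates an upstream extraction problem).
#' @param subject_id Character scalar.
#' @param label `"MDD"` or `"NC"` (case-insensitive).
#' @param site_id Character scalar identifying the acquisition site.
#' @return An object of class `roi_ts`.
#' @examples
#' ts <- roi_time_series(matrix(rnorm(5 * 30), 5), "s1", "MDD", "siteA")
#' dim(ts$signals)
#' @export
roi_time_series <- function(signals, subject_id, label, site_id = "site1") {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  label <- normalize_label(label)
  obj <- structure(
    list(signals = signals, subject_id = as.character(subject_id),
         label = label, site_id = as.character(site_id)),
    class = "roi_ts")
  validate_roi_ts(obj)
  obj
}

normalize_label <- function(label) {
  lab <- toupper(as.character(label))
  if (!lab %in% c("MDD", "NC")) {
    stop("unknown label '", label, "': expected 'MDD' or 'NC'", call. = FALSE)
  }
  lab
}

validate_roi_ts <- function(ts) {
  sig <- ts$signals
  if (nrow(sig) < 2) stop("need at least 2 ROIs, got ", nrow(sig), call. = FALSE)
  if (ncol(sig) < 3) {
    stop("need at least 3 time points, got ", ncol(sig), call. = FALSE)
  }
  if (anyNA(sig) || any(!is.finite(sig))) {
    stop("signals contain missing or non-finite values (subject ",
         ts$subject_id, ")", call. = FALSE)
  }
  v <- apply(sig, 1, stats::var)
  if (any(v == 0)) {
    stop("ROI ", which(v == 0)[1], " has zero variance (subject ",
         ts$subject_id, "): Pearson correlation undefined", call. = FALSE)
  }
  invisible(ts)
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s  label %s  site %s  %d ROIs x %d time points\n",
              x$subject_id, x$label, x$site_id, nrow(x$signals), ncol(x$signals)))
  invisible(x)
}

#' Pearson functional-connectivity matrix
#'
#' Computes the ROI-by-ROI Pearson correlation matrix of a subject's time
#' series: entry (i, j) is the correlation between the signal of region i and
#' region j across time. The result is symmetric with unit diagonal and all
#' entries in \[-1, 1\].
#'
#' @param ts A [roi_time_series()] object, or a plain numeric matrix of
#'   signals (`n_rois x T`).
#' @return A `fc_matrix`: the correlation matrix carrying the subject's
#'   metadata as attributes (`subject_id`, `label`, `site_id`).
#' @examples
#' ts <- roi_time_series(matrix(rnorm(4 * 50), 4), "s1", "NC")
#' fc <- pearson_fc(ts)
#' all(abs(fc) <= 1); all(diag(fc) == 1)
#' @export
pearson_fc <- function(ts) {
  if (is.matrix(ts)) ts <- roi_time_series(ts, "anonymous", "NC")
  stopifnot(inherits(ts, "roi_ts"))
  validate_roi_ts(ts)
  r <- stats::cor(t(ts$signals))
  # cor() can stray from exactly 1 on the diagonal by rounding; pin it
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  fc_matrix(r, subject_id = ts$subject_id, label = ts$label,
            site_id = ts$site_id)
}

#' Construct a functional-connectivity matrix object
#'
#' Wraps a precomputed correlation matrix (e.g. shipped by a consortium
#' instead of raw time series) with subject metadata, after validating the
#' correlation-matrix invariants.
#'
#' @param values Symmetric numeric matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @inheritParams roi_time_series
#' @return A `fc_matrix` object.
#' @export
fc_matrix <- function(values, subject_id = "anonymous", label = "NC",
                      site_id = "site1") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("FC matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8) {
    stop("FC matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(values) > 1 + 1e-8)) {
    stop("FC entries must lie in [-1, 1]", call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > 1e-8)) {
    stop("FC diagonal must equal 1", call. = FALSE)
  }
  structure(values, class = c("fc_matrix", "matrix"),
            subject_id = as.character(subject_id),
            label = normalize_label(label), site_id = as.character(site_id))
}

#' Threshold a correlation matrix into a binary adjacency matrix
#'
#' Sparsifies a functional-connectivity matrix: an undirected edge connects
#' ROIs i and j (i != j) when their correlation reaches the threshold. By
#' default the *signed* correlation is compared (`fc[i, j] >= tau`), so
#' negative correlations never produce edges; set `absolute = TRUE` to
#' threshold `|fc[i, j]|` instead. The comparison is inclusive, so exact ties
#' at the threshold are kept deterministically.
#'
#' @param fc A `fc_matrix` (or plain square symmetric matrix).
#' @param tau Threshold in (0, 1).
#' @param absolute Threshold the absolute correlation instead of the signed
#'   value. Default `FALSE`.
#' @return A `binary_adjacency`: 0/1 matrix with zero diagonal, carrying
#'   attributes `threshold` and `edge_count` (number of undirected edges).
#' @examples
#' fc <- matrix(c(1, .35, .1, .35, 1, .25, .1, .25, 1), 3)
#' adj <- threshold_binarize(fc_matrix(fc), 0.3)
#' edge_count(adj)  # 1
#' @export
threshold_binarize <- function(fc, tau, absolute = FALSE) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0 || tau >= 1) {
    stop("tau must be a single number in (0, 1)", call. = FALSE)
  }
  v <- unclass(fc)
  cmp <- if (absolute) abs(v) else v
  a <- (cmp >= tau) * 1L
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  structure(a, class = c("binary_adjacency", "matrix"),
            threshold = tau,
            edge_count = sum(a) %/% 2L,
            subject_id = attr(fc, "subject_id"),
            label = attr(fc, "label"),
            site_id = attr(fc, "site_id"))
}

#' Number of undirected edges of a binary adjacency matrix
#' @param adj A `binary_adjacency` or plain 0/1 symmetric matrix.
#' @return Integer edge count.
#' @export
edge_count <- function(adj) {
  ec <- attr(adj, "edge_count")
  if (is.null(ec)) ec <- sum(unclass(adj) != 0) %/% 2L
  as.integer(ec)
}

validate_adjacency <- function(adj) {
  a <- unclass(adj)
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (any(a != 0 & a != 1)) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (any(a != t(a))) stop("adjacency must be symmetric", call. = FALSE)
  invisible(adj)
}

#' Assemble the classifier input graph
#'
#' Combines a subject's binary adjacency (graph structure) with continuous
#' node features. By default node i's feature vector is row i of the
#' *continuous* correlation matrix — its whole-brain connectivity profile —
#' so the classifier sees edge topology and connection strengths; set
#' `features = "binary"` to use rows of the binary matrix instead.
#'
#' @param fc The subject's `fc_matrix`.
#' @param adj The corresponding `binary_adjacency`; if `NULL`, computed from
#'   `fc` at threshold `tau`.
#' @param tau Threshold used when `adj` is `NULL`.
#' @param label,site_id Override the metadata carried on `fc`.
#' @param features `"weighted"` (rows of the continuous FC matrix, default)
#'   or `"binary"` (rows of the adjacency).
#' @return A `brain_graph`: list with `adjacency`, `features` (n x n matrix),
#'   `label`, `site_id`, `subject_id`.
#' @export
build_graph <- function(fc, adj = NULL, tau = 0.3, label = NULL,
                        site_id = NULL, features = c("weighted", "binary")) {
  features <- match.arg(features)
  if (is.null(adj)) adj <- threshold_binarize(fc, tau)
  validate_adjacency(adj)
  if (!all(dim(unclass(fc)) == dim(unclass(adj)))) {
    stop("FC matrix and adjacency dimensions differ", call. = FALSE)
  }
  feat <- if (features == "weighted") unclass(fc) else unclass(adj) * 1
  feat <- matrix(as.numeric(feat), nrow(feat))
  structure(
    list(adjacency = adj,
         features = feat,
         label = normalize_label(label %||% attr(fc, "label") %||% "NC"),
         site_id = as.character(site_id %||% attr(fc, "site_id") %||% "site1"),
         subject_id = as.character(attr(fc, "subject_id") %||% "anonymous")),
    class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> subject %s  label %s  site %s  %d nodes, %d edges (tau=%s)\n",
              x$subject_id, x$label, x$site_id, nrow(x$features),
              edge_count(x$adjacency),
              format(attr(x$adjacency, "threshold"))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
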