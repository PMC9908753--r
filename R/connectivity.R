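#' Transitive closure by the Warshall recursion
#'
#' Runs the Boolean Warshall recursion
#' `R_k[i, j] = R_{k-1}[i, j] OR (R_{k-1}[i, k] AND R_{k-1}[k, j])`
#' over all pivot nodes k, starting from the adjacency with the diagonal set
#' true (every node reaches itself). Entry (i, j) of the result is `TRUE` iff
#' node j is reachable from node i. The inner i,j sweep for each pivot is
#' vectorized as an outer product, which is the same recursion evaluated in
#' one shot.
#'
#' @param adj A `binary_adjacency` (or plain 0/1 matrix with zero diagonal).
#' @return Logical n x n matrix of class `reachability`.
#' @examples
#' path <- matrix(0L, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
#' all(warshall_closure(path))  # a path graph is connected
#' @export
warshall_closure <- function(adj) {
  validate_adjacency(adj)
  r <- unclass(adj) != 0
  diag(r) <- TRUE
  n <- nrow(r)
  for (k in seq_len(n)) {
    r <- r | outer(r[, k], r[k, ], "&")
  }
  structure(r, class = c("reachability", "matrix"))
}

#' Is a graph connected?
#'
#' A graph is connected when every ordered pair of distinct nodes is mutually
#' reachable, i.e. every off-diagonal entry of the transitive closure is true.
#'
#' @param x A `reachability` matrix from [warshall_closure()], or a
#'   `binary_adjacency` (closure computed internally).
#' @return Logical scalar.
#' @export
is_connected <- function(x) {
  if (!inherits(x, "reachability")) x <- warshall_closure(x)
  all(x)
}

#' Cohort connectivity ratio
#'
#' The number of connected brain networks divided by the number of
#' unconnected ones at a given threshold. When every network is connected
#' (typical at low thresholds) the ratio is reported as `Inf` rather than
#' failing, so threshold sweeps always complete.
#'
#' @param adjs Nonempty list of `binary_adjacency` matrices.
#' @return Numeric ratio (possibly `Inf`).
#' @export
connectivity_ratio <- function(adjs) {
  if (length(adjs) == 0) stop("empty collection of graphs", call. = FALSE)
  conn <- vapply(adjs, is_connected, logical(1))
  n_unconn <- sum(!conn)
  if (n_unconn == 0) return(Inf)
  sum(conn) / n_unconn
}

#' Per-threshold connectivity summary table
#'
#' For each threshold, binarizes every subject's FC matrix and reports the
#' connected/unconnected counts, the connectivity ratio (overall and per
#' diagnostic group) and the mean edge count per group — the cohort-level
#' sparsity/connectivity profile used to choose a working threshold.
#'
#' @param fcs List of `fc_matrix` objects (with `label` attributes).
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param absolute Passed to [threshold_binarize()].
#' @return `data.frame` with one row per threshold: `threshold`,
#'   `n_connected`, `n_unconnected`, `ratio`, `ratio_MDD`, `ratio_NC`,
#'   `mean_edges_MDD`, `mean_edges_NC`.
#' @export
connectivity_table <- function(fcs, thresholds = c(0.2, 0.3, 0.4),
                               absolute = FALSE) {
  stopifnot(length(fcs) > 0)
  labels <- vapply(fcs, function(f) attr(f, "label") %||% "NC", character(1))
  rows <- lapply(thresholds, function(tau) {
    adjs <- lapply(fcs, threshold_binarize, tau = tau, absolute = absolute)
    conn <- vapply(adjs, is_connected, logical(1))
    edges <- vapply(adjs, edge_count, integer(1))
    ratio_for <- function(keep) {
      if (!any(keep)) return(NA_real_)
      if (all(conn[keep])) Inf else sum(conn[keep]) / sum(!conn[keep])
    }
    data.frame(
      threshold = tau,
      n_connected = sum(conn),
      n_unconnected = sum(!conn),
      ratio = ratio_for(rep(TRUE, length(conn))),
      ratio_MDD = ratio_for(labels == "MDD"),
      ratio_NC = ratio_for(labels == "NC"),
      mean_edges_MDD = if (any(labels == "MDD")) mean(edges[labels == "MDD"]) else NA_real_,
      mean_edges_NC = if (any(labels == "NC")) mean(edges[labels == "NC"]) else NA_real_)
  })
  do.call(rbind, rows)
}
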