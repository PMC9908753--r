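# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive re-derivations (loops, brute force) so they
# stay independent of the package's vectorized implementations.

# two-pass Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# breadth-first-search reachability matrix (reflexive)
oracle_bfs_reachability <- function(a) {
  n <- nrow(a)
  r <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n)
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(a[v, ] != 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    r[s, ] <- seen
  }
  r
}

# union-find connected-component count
oracle_component_count <- function(a) {
  n <- nrow(a)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (a[i, j] != 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Mann-Whitney pair statistic, ties counted 1/2
oracle_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# full lexicographic descending row sort (right-to-left keys, then index)
oracle_sortpool_order <- function(x) {
  n <- nrow(x); C <- ncol(x)
  better <- function(i, j) {
    for (c in rev(seq_len(C))) {
      if (x[i, c] != x[j, c]) return(x[i, c] > x[j, c])
    }
    i < j
  }
  ord <- seq_len(n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (better(ord[b], ord[a])) { tmp <- ord[a]; ord[a] <- ord[b]; ord[b] <- tmp }
  }
  ord
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

as_binary_adjacency <- function(a, tau = 0.5) {
  structure(a, class = c("binary_adjacency", "matrix"), threshold = tau,
            edge_count = sum(a) %/% 2L)
}

# small brain graphs with random PSD-backed FC structure
tiny_graphs <- function(n_subj = 6, n_rois = 12, T_len = 60, delta = 0.3,
                        seed = 3, tau = 0.3) {
  spec <- synthetic_cohort_spec(n_per_group = ceiling(n_subj / 2),
                                n_rois = n_rois, T_len = T_len,
                                n_blocks = 3, effect_delta = delta,
                                site_count = 2, seed = seed)
  cohort_to_graphs(generate_cohort(spec), tau = tau)[seq_len(n_subj)]
}

# small config whose head fits tiny graphs; ... overrides any default
tiny_config <- function(n_rois = 12, ...) {
  args <- list(conv_channels = c(4, 3, 2, 1), filters1 = 3, filters2 = 4,
               width2 = 2, dense_width = 8, dropout = 0, epochs = 3,
               batch_size = 4, seed = 7, k = n_rois)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dgcnn_config, args)
}

# generic parameter point: Glorot weights plus small random biases so no
# ReLU pre-activation sits exactly on its kink
generic_params <- function(config, in_channels, seed = 11) {
  set.seed(seed)
  params <- dgcnn_init(config, in_channels)
  for (nm in grep("^b", names(params), value = TRUE)) {
    params[[nm]] <- stats::rnorm(length(params[[nm]]), sd = 0.1)
  }
  params
}

permute_graph <- function(g, perm) {
  g$adjacency <- structure(unclass(g$adjacency)[perm, perm],
                           class = class(g$adjacency),
                           threshold = attr(g$adjacency, "threshold"),
                           edge_count = attr(g$adjacency, "edge_count"))
  g$features <- g$features[perm, , drop = FALSE]
  g
}
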