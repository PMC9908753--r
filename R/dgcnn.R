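#' DGCNN hyperparameter configuration
#'
#' Architecture and training hyperparameters of the deep graph convolutional
#' neural network. The defaults follow the standard DGCNN stack: four graph
#' convolutions with tanh activations and channel widths 32/32/32/1, whose
#' concatenated outputs pass through SortPooling into a 1-D convolutional
#' head (16 filters spanning one node's channel vector, max-pool 2/2, then 32
#' filters of width 5 with ReLU), a 128-unit dense layer with ReLU, dropout
#' 0.5 between the two dense layers, and a 2-way softmax output. Training
#' uses binary cross-entropy, Adam, mini-batches of 50 for 100 epochs; the
#' learning rate (default 0.001) is the main hyperparameter to tune.
#'
#' @param conv_channels Integer vector of graph-convolution output widths.
#' @param k SortPooling size: number of (sorted) nodes kept. `NULL` (default)
#'   means "use the graph's node count", natural here because all brain
#'   graphs share one atlas and hence one size.
#' @param filters1 Filters of the first 1-D convolution stage; its width and
#'   stride both equal `sum(conv_channels)`, i.e. it reads one node's
#'   concatenated channel vector per step.
#' @param filters2,width2 Filters and width of the second 1-D convolution
#'   stage (stride 1).
#' @param pool Width and stride of the max-pooling between the two stages.
#' @param dense_width Units of the penultimate dense layer.
#' @param dropout Dropout rate applied between the two dense layers, in
#'   \[0, 1). Inverted convention: activations are rescaled at train time so
#'   evaluation uses the raw weights.
#' @param learning_rate,epochs,batch_size,seed Optimizer settings. `seed`
#'   drives weight initialization, mini-batch shuffling and dropout, making
#'   training bit-reproducible.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and stabilizer.
#' @return A `dgcnn_config` list.
#' @export
dgcnn_config <- function(conv_channels = c(32L, 32L, 32L, 1L), k = NULL,
                         filters1 = 16L, filters2 = 32L, width2 = 5L,
                         pool = 2L, dense_width = 128L, dropout = 0.5,
                         learning_rate = 0.001, epochs = 100L,
                         batch_size = 50L, seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(length(conv_channels) >= 1, all(conv_channels >= 1),
            is.null(k) || k >= 1, filters1 >= 1, filters2 >= 1, width2 >= 1,
            pool >= 1, dense_width >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(
    conv_channels = as.integer(conv_channels),
    k = if (is.null(k)) NULL else as.integer(k),
    filters1 = as.integer(filters1), filters2 = as.integer(filters2),
    width2 = as.integer(width2), pool = as.integer(pool),
    dense_width = as.integer(dense_width), dropout = dropout,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps),
    class = "dgcnn_config")
}

# head geometry implied by config for SortPooling size k
dgcnn_geometry <- function(config, k) {
  C <- sum(config$conv_channels)
  k2 <- k %/% config$pool
  L <- k2 - config$width2 + 1L
  if (L < 1) {
    stop("SortPooling size k=", k, " too small for the convolutional head ",
         "(need floor(k/", config$pool, ") >= ", config$width2,
         "); reduce width2 or increase k", call. = FALSE)
  }
  list(C = C, k2 = k2, L = L)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize DGCNN parameters
#'
#' Uniform Glorot (fan-based) initialization of every weight matrix; biases
#' start at zero. Consumes the current RNG stream, so call after `set.seed()`
#' for reproducibility (done automatically inside [train_dgcnn()]).
#'
#' @param config A [dgcnn_config()].
#' @param in_channels Node-feature dimension d (equals the node count when
#'   features are FC-matrix rows).
#' @param k SortPooling size; defaults to `config$k`.
#' @return Named list of parameter arrays (`Wg1`..`WgT` graph-conv weights,
#'   `W1`/`b1` and `W2`/`b2` conv head, `W3`/`b3` and `W4`/`b4` dense layers).
#' @export
dgcnn_init <- function(config, in_channels, k = config$k) {
  stopifnot(!is.null(k))
  geo <- dgcnn_geometry(config, k)
  ch <- config$conv_channels
  fan_in <- c(in_channels, ch[-length(ch)])
  params <- list()
  for (t in seq_along(ch)) {
    params[[paste0("Wg", t)]] <- glorot(fan_in[t], ch[t])
  }
  params$W1 <- glorot(geo$C, config$filters1)
  params$b1 <- numeric(config$filters1)
  params$W2 <- glorot(config$width2 * config$filters1, config$filters2)
  params$b2 <- numeric(config$filters2)
  params$W3 <- glorot(geo$L * config$filters2, config$dense_width)
  params$b3 <- numeric(config$dense_width)
  params$W4 <- glorot(config$dense_width, 2L)
  params$b4 <- numeric(2L)
  params
}

check_params <- function(params, config, in_channels, k) {
  geo <- dgcnn_geometry(config, k)
  ch <- config$conv_channels
  fan_in <- c(in_channels, ch[-length(ch)])
  for (t in seq_along(ch)) {
    w <- params[[paste0("Wg", t)]]
    if (is.null(w) || !all(dim(w) == c(fan_in[t], ch[t]))) {
      stop("graph-conv weight Wg", t, " has inconsistent shape", call. = FALSE)
    }
  }
  if (!all(dim(params$W1) == c(geo$C, config$filters1)) ||
      !all(dim(params$W2) == c(config$width2 * config$filters1, config$filters2)) ||
      !all(dim(params$W3) == c(geo$L * config$filters2, config$dense_width)) ||
      !all(dim(params$W4) == c(config$dense_width, 2L))) {
    stop("head parameters inconsistent with config/graph size", call. = FALSE)
  }
  invisible(TRUE)
}

#' Single graph-convolution layer
#'
#' One degree-normalized propagation step
#' `Z_out = tanh(D^-1 (A + I) Z_in W)`: each node averages its own and its
#' neighbours' feature vectors (the added identity is the self-loop; D is the
#' diagonal degree matrix of A + I), mixes channels through W and applies the
#' hyperbolic tangent.
#'
#' @param adj Binary adjacency with zero diagonal (`binary_adjacency` or
#'   plain matrix).
#' @param features Numeric matrix, nodes x in-channels.
#' @param weights Numeric matrix, in-channels x out-channels.
#' @return Numeric matrix, nodes x out-channels, entries in (-1, 1).
#' @export
graph_conv_layer <- function(adj, features, weights) {
  validate_adjacency(adj)
  features <- as.matrix(features)
  weights <- as.matrix(weights)
  if (nrow(features) != nrow(unclass(adj))) {
    stop("feature rows must match node count", call. = FALSE)
  }
  if (ncol(features) != nrow(weights)) {
    stop("feature columns must match weight rows", call. = FALSE)
  }
  p <- prop_matrix(unclass(adj))
  tanh(p %*% features %*% weights)
}

# D^-1 (A + I): row-normalized adjacency with self-loops
prop_matrix <- function(a) {
  at <- unclass(a) + diag(nrow(a))
  at / rowSums(at)
}

# order of rows under SortPooling: descending by last channel, ties broken by
# earlier channels right-to-left, then ascending node index
sort_order <- function(x) {
  n <- nrow(x)
  C <- ncol(x)
  ord <- order(x[, C], seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  if (anyDuplicated(x[, C])) {
    keys <- lapply(rev(seq_len(C)), function(j) -x[, j])
    ord <- do.call(order, c(keys, list(seq_len(n))))
  }
  ord
}

#' SortPooling
#'
#' Sorts node rows into a canonical order — descending by the last feature
#' channel, ties broken by the preceding channels right to left, then by node
#' index — and emits exactly `k` rows: the top `k` if the graph has more
#' nodes, zero-padded at the bottom if it has fewer. The canonical order
#' makes the downstream 1-D convolutional layers invariant to the input
#' node ordering.
#'
#' @param x Numeric matrix, nodes x channels (the concatenated graph-conv
#'   outputs).
#' @param k Positive integer output size.
#' @return Numeric `k x ncol(x)` matrix.
#' @export
sort_pooling <- function(x, k) {
  x <- as.matrix(x)
  stopifnot(k >= 1)
  ord <- sort_order(x)
  m <- min(nrow(x), k)
  out <- matrix(0, k, ncol(x))
  out[seq_len(m), ] <- x[ord[seq_len(m)], , drop = FALSE]
  out
}

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-(y log p + (1 - y) log(1 - p))`, where `p` is the
#' predicted probability of the positive (MDD) class. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` to keep the logarithms finite.
#'
#' @param probs Numeric vector of positive-class probabilities, or a
#'   two-column probability matrix (second column = positive class).
#' @param labels Numeric/integer vector of 0/1 (1 = positive class).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(probs, labels) {
  if (is.matrix(probs)) probs <- probs[, 2]
  if (length(probs) == 0) stop("empty batch", call. = FALSE)
  if (length(probs) != length(labels)) stop("length mismatch", call. = FALSE)
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)))
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- batched forward/backward over equal-sized graphs ----------------------

# Block-diagonal propagation: out rows for graph g are P[[g]] %*% z rows of g.
# A plain loop over the small dense per-graph blocks beats building a sparse
# block-diagonal matrix by a wide margin at these sizes.
block_mult <- function(P, z, n, transpose = FALSE) {
  out <- matrix(0, nrow(z), ncol(z))
  for (g in seq_along(P)) {
    rg <- ((g - 1L) * n + 1L):(g * n)
    out[rg, ] <- if (transpose) crossprod(P[[g]], z[rg, , drop = FALSE])
      else P[[g]] %*% z[rg, , drop = FALSE]
  }
  out
}

# Precompute the stacked representation of a graph set: row-normalized
# propagation matrices, stacked features, numeric labels (MDD = 1).
prep_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  ns <- vapply(graphs, function(g) nrow(g$features), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all graphs in a batch must have the same node count", call. = FALSE)
  }
  n <- ns[1]
  d <- ncol(graphs[[1]]$features)
  list(
    P = lapply(graphs, function(g) prop_matrix(unclass(g$adjacency))),
    X = do.call(rbind, lapply(graphs, function(g) g$features)),
    y = vapply(graphs, function(g) as.numeric(g$label == "MDD"), numeric(1)),
    site = vapply(graphs, function(g) g$site_id, character(1)),
    n = n, d = d, B = length(graphs))
}

# index helpers for the head, per batch size B
head_indices <- function(B, n, k, geo, pool, width2) {
  base_n <- rep((seq_len(B) - 1L) * n, each = n)
  base_k2 <- rep((seq_len(B) - 1L) * geo$k2, each = geo$L)
  list(
    iodd = rep((seq_len(B) - 1L) * k, each = geo$k2) +
      rep(seq(1L, by = pool, length.out = geo$k2), B),
    ieven = rep((seq_len(B) - 1L) * k, each = geo$k2) +
      rep(seq(pool, by = pool, length.out = geo$k2), B),
    unfold = lapply(0:(width2 - 1L),
                    function(w) base_k2 + rep(seq_len(geo$L) + w, B)))
}

# Full forward pass on a prepared batch. mode "train" applies (inverted)
# dropout using the current RNG stream. Returns probabilities and, if
# keep_cache, every intermediate needed by the backward pass.
dgcnn_forward_batch <- function(prep, params, config, mode = "eval",
                                keep_cache = FALSE) {
  n <- prep$n; B <- prep$B
  k <- config$k %||% n
  geo <- dgcnn_geometry(config, k)
  check_params(params, config, prep$d, k)
  nlayer <- length(config$conv_channels)

  A <- vector("list", nlayer); Z <- vector("list", nlayer)
  zprev <- prep$X
  for (t in seq_len(nlayer)) {
    A[[t]] <- block_mult(prep$P, zprev, n)
    Z[[t]] <- tanh(A[[t]] %*% params[[paste0("Wg", t)]])
    zprev <- Z[[t]]
  }
  Zcat <- do.call(cbind, Z)

  # SortPooling: per-graph canonical row order, truncate/pad to k rows
  m <- min(n, k)
  sel <- integer(B * m)     # source rows in Zcat
  dst <- integer(B * m)     # destination rows in the pooled matrix
  for (g in seq_len(B)) {
    rg <- ((g - 1L) * n + 1L):(g * n)
    ord <- sort_order(Zcat[rg, , drop = FALSE])
    ix <- ((g - 1L) * m + 1L):(g * m)
    sel[ix] <- rg[ord[seq_len(m)]]
    dst[ix] <- (g - 1L) * k + seq_len(m)
  }
  Zp <- matrix(0, B * k, geo$C)
  Zp[dst, ] <- Zcat[sel, , drop = FALSE]

  idx <- head_indices(B, n, k, geo, config$pool, config$width2)
  H1pre <- sweep(Zp %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(H1pre, 0)
  Ha <- H1[idx$iodd, , drop = FALSE]
  Hb <- H1[idx$ieven, , drop = FALSE]
  amax <- Ha >= Hb
  Hp <- pmax(Ha, Hb)
  U <- do.call(cbind, lapply(idx$unfold, function(iw) Hp[iw, , drop = FALSE]))
  H2pre <- sweep(U %*% params$W2, 2, params$b2, "+")
  H2 <- pmax(H2pre, 0)
  Fl <- matrix(aperm(array(H2, c(geo$L, B, config$filters2)), c(2, 1, 3)),
               B, geo$L * config$filters2)
  H3pre <- sweep(Fl %*% params$W3, 2, params$b3, "+")
  H3 <- pmax(H3pre, 0)
  if (mode == "train" && config$dropout > 0) {
    Mdrop <- matrix(
      (stats::runif(length(H3)) >= config$dropout) / (1 - config$dropout),
      nrow(H3), ncol(H3))
    H3d <- H3 * Mdrop
  } else {
    Mdrop <- NULL
    H3d <- H3
  }
  logits <- sweep(H3d %*% params$W4, 2, params$b4, "+")
  e <- exp(logits - apply(logits, 1, max))
  probs <- e / rowSums(e)
  colnames(probs) <- c("NC", "MDD")

  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(A = A, Z = Z, sel = sel, dst = dst, Zp = Zp,
                      idx = idx, H1pre = H1pre, amax = amax, U = U,
                      H2pre = H2pre, Fl = Fl, H3pre = H3pre, H3d = H3d,
                      Mdrop = Mdrop, geo = geo, k = k)
  }
  out
}

# Backward pass: gradients of the batch-mean BCE loss w.r.t. every parameter.
dgcnn_backward_batch <- function(prep, params, config, fwd) {
  cc <- fwd$cache
  geo <- cc$geo
  B <- prep$B; n <- prep$n; k <- cc$k
  y <- prep$y
  eps <- 1e-7
  u <- fwd$probs[, 2]
  inside <- u > eps & u < 1 - eps
  uc <- pmin(pmax(u, eps), 1 - eps)
  gy <- ifelse(inside, (-y / uc + (1 - y) / (1 - uc)) / B, 0)
  dl2 <- unname(gy * u * (1 - u))    # d loss / d logit_MDD
  dlogits <- cbind(-dl2, dl2, deparse.level = 0)

  grads <- list()
  grads$W4 <- crossprod(cc$H3d, dlogits)
  grads$b4 <- colSums(dlogits)
  dH3d <- dlogits %*% t(params$W4)
  dH3 <- if (is.null(cc$Mdrop)) dH3d else dH3d * cc$Mdrop
  dH3pre <- dH3 * (cc$H3pre > 0)
  grads$W3 <- crossprod(cc$Fl, dH3pre)
  grads$b3 <- colSums(dH3pre)
  dFl <- dH3pre %*% t(params$W3)

  dH2 <- matrix(aperm(array(dFl, c(B, geo$L, config$filters2)), c(2, 1, 3)),
                B * geo$L, config$filters2)
  dH2pre <- dH2 * (cc$H2pre > 0)
  grads$W2 <- crossprod(cc$U, dH2pre)
  grads$b2 <- colSums(dH2pre)
  dU <- dH2pre %*% t(params$W2)

  F1 <- config$filters1
  dHp <- matrix(0, B * geo$k2, F1)
  for (w in seq_along(cc$idx$unfold)) {
    cols <- ((w - 1L) * F1 + 1L):(w * F1)
    iw <- cc$idx$unfold[[w]]
    dHp[iw, ] <- dHp[iw, ] + dU[, cols, drop = FALSE]
  }
  dH1 <- matrix(0, B * k, F1)
  dH1[cc$idx$iodd, ] <- dHp * cc$amax
  dH1[cc$idx$ieven, ] <- dHp * (!cc$amax)
  dH1pre <- dH1 * (cc$H1pre > 0)
  grads$W1 <- crossprod(cc$Zp, dH1pre)
  grads$b1 <- colSums(dH1pre)
  dZp <- dH1pre %*% t(params$W1)

  dZcat <- matrix(0, B * n, geo$C)
  dZcat[cc$sel, ] <- dZp[cc$dst, , drop = FALSE]

  ch <- config$conv_channels
  nlayer <- length(ch)
  col_hi <- cumsum(ch)
  col_lo <- col_hi - ch + 1L
  carry <- NULL                       # gradient flowing from layer above
  for (t in rev(seq_len(nlayer))) {
    dZt <- dZcat[, col_lo[t]:col_hi[t], drop = FALSE]
    if (!is.null(carry)) dZt <- dZt + carry
    dSt <- dZt * (1 - cc$Z[[t]]^2)
    grads[[paste0("Wg", t)]] <- crossprod(cc$A[[t]], dSt)
    if (t > 1) {
      carry <- block_mult(prep$P, dSt %*% t(params[[paste0("Wg", t)]]),
                          n, transpose = TRUE)
    }
  }
  grads[names(params)]
}

#' Loss and analytic gradients on a set of graphs
#'
#' Evaluates the batch-mean binary cross-entropy and its analytic gradient
#' with respect to every parameter array, with dropout disabled so the
#' result is deterministic — the workhorse for finite-difference gradient
#' verification.
#'
#' @param graphs List of `brain_graph` objects (equal node counts).
#' @param params Parameter list from [dgcnn_init()].
#' @param config A [dgcnn_config()].
#' @return List with elements `loss` (scalar) and `grads` (named list
#'   matching `params`).
#' @export
dgcnn_gradients <- function(graphs, params, config) {
  prep <- prep_graphs(graphs)
  cfg <- config
  cfg$dropout <- 0
  if (is.null(cfg$k)) cfg$k <- prep$n
  fwd <- dgcnn_forward_batch(prep, params, cfg, mode = "eval", keep_cache = TRUE)
  list(loss = bce_loss(fwd$probs, prep$y),
       grads = dgcnn_backward_batch(prep, params, cfg, fwd))
}

#' DGCNN forward pass on one graph
#'
#' @param graph A `brain_graph`.
#' @param params Parameter list from [dgcnn_init()] or a trained model.
#' @param config A [dgcnn_config()].
#' @param mode `"eval"` (deterministic, dropout off — the default) or
#'   `"train"` (stochastic inverted dropout drawn from the current RNG).
#' @return Named numeric vector `c(NC = p0, MDD = p1)` summing to 1.
#' @export
dgcnn_forward <- function(graph, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  prep <- prep_graphs(list(graph))
  cfg <- config
  if (is.null(cfg$k)) cfg$k <- prep$n
  fwd <- dgcnn_forward_batch(prep, params, cfg, mode = mode)
  fwd$probs[1, ]
}

# ---- training --------------------------------------------------------------

adam_update <- function(params, grads, state, lr, b1, b2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_split <- function(prep, params, config) {
  fwd <- dgcnn_forward_batch(prep, params, config, mode = "eval")
  p <- fwd$probs[, 2]
  list(loss = bce_loss(p, prep$y),
       acc = mean((p >= 0.5) == (prep$y == 1)))
}

#' Train the DGCNN classifier
#'
#' Mini-batch Adam training with binary cross-entropy on a set of brain
#' graphs. Mini-batches are reshuffled every epoch; after each epoch the full
#' training set (and validation set, if given) is re-evaluated in eval mode
#' to record the loss/accuracy history. All randomness (initialization,
#' shuffling, dropout) derives from `config$seed`, so two runs with the same
#' inputs and config are bit-identical.
#'
#' @param train_graphs Nonempty list of `brain_graph` objects containing both
#'   classes.
#' @param val_graphs Optional validation list.
#' @param config A [dgcnn_config()].
#' @param init Optional pre-initialized parameter list (overrides the seeded
#'   Glorot initialization).
#' @param verbose Emit a per-epoch log line via [log_event()].
#' @return A `dgcnn_model`: list with `params`, `config` (with `k` resolved),
#'   and `history` (data.frame: epoch, train_loss, train_acc, val_loss,
#'   val_acc).
#' @export
train_dgcnn <- function(train_graphs, val_graphs = NULL, config = dgcnn_config(),
                        init = NULL, verbose = FALSE) {
  prep <- prep_graphs(train_graphs)
  if (length(unique(prep$y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  cfg <- config
  if (is.null(cfg$k)) cfg$k <- prep$n
  set.seed(cfg$seed)
  params <- init %||% dgcnn_init(cfg, prep$d)
  check_params(params, cfg, prep$d, cfg$k)
  vprep <- if (!is.null(val_graphs) && length(val_graphs) > 0) {
    prep_graphs(val_graphs)
  }
  state <- list(t = 0L,
                m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
                v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
  # keep vector-shaped biases vector-shaped
  for (nm in names(params)) {
    if (is.null(dim(params[[nm]]))) {
      state$m[[nm]] <- numeric(length(params[[nm]]))
      state$v[[nm]] <- numeric(length(params[[nm]]))
    }
  }
  nb <- ceiling(prep$B / cfg$batch_size)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(prep$B)
    for (b in seq_len(nb)) {
      ix <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, prep$B)]
      sub <- list(P = prep$P[ix], y = prep$y[ix],
                  X = prep$X[rep((ix - 1L) * prep$n, each = prep$n) +
                               rep(seq_len(prep$n), length(ix)), , drop = FALSE],
                  n = prep$n, d = prep$d, B = length(ix))
      fwd <- dgcnn_forward_batch(sub, params, cfg, mode = "train",
                                 keep_cache = TRUE)
      grads <- dgcnn_backward_batch(sub, params, cfg, fwd)
      upd <- adam_update(params, grads, state, cfg$learning_rate,
                         cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
      params <- upd$params
      state <- upd$state
    }
    tr <- eval_split(prep, params, cfg)
    va <- if (!is.null(vprep)) eval_split(vprep, params, cfg) else
      list(loss = NA_real_, acc = NA_real_)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr$loss,
                             train_acc = tr$acc, val_loss = va$loss,
                             val_acc = va$acc)
    if (verbose) {
      log_event("DEBUG", "train",
                sprintf("epoch %d/%d train_loss=%.4f train_acc=%.3f",
                        ep, cfg$epochs, tr$loss, tr$acc))
    }
  }
  structure(list(params = params, config = cfg,
                 history = do.call(rbind, hist)),
            class = "dgcnn_model")
}

#' @export
print.dgcnn_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<dgcnn_model> %d graph-conv layers (C=%d), k=%d | %d epochs, final train_loss=%.4f train_acc=%.3f\n",
    length(x$config$conv_channels), sum(x$config$conv_channels), x$config$k,
    nrow(x$history), h$train_loss, h$train_acc))
  invisible(x)
}

#' Predict class probabilities for brain graphs
#'
#' Deterministic eval-mode forward pass on each graph, order preserved.
#'
#' @param object A `dgcnn_model` from [train_dgcnn()].
#' @param graphs List of `brain_graph` objects (may be empty).
#' @param ... Unused.
#' @return `data.frame` with columns `subject_id`, `p_NC`, `p_MDD`, `pred`
#'   (argmax label).
#' @export
predict.dgcnn_model <- function(object, graphs, ...) {
  if (length(graphs) == 0) {
    return(data.frame(subject_id = character(0), p_NC = numeric(0),
                      p_MDD = numeric(0), pred = character(0)))
  }
  prep <- prep_graphs(graphs)
  fwd <- dgcnn_forward_batch(prep, object$params, object$config, mode = "eval")
  data.frame(
    subject_id = vapply(graphs, function(g) g$subject_id, character(1)),
    p_NC = fwd$probs[, 1], p_MDD = fwd$probs[, 2],
    pred = ifelse(fwd$probs[, 2] >= fwd$probs[, 1], "MDD", "NC"))
}
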