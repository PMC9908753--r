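#' Synthetic cohort specification
#'
#' Describes a two-group, multi-site cohort of ROI time series whose group
#' difference is a controlled perturbation of the inter-regional correlation
#' structure: ROIs are organized into equally sized blocks (functional
#' communities) with correlation `base_within_r` inside a block and
#' `base_between_r` across blocks; case subjects get `effect_delta` added to
#' their within-block correlations, and each site adds a global offset to all
#' off-diagonal correlations (evenly spaced in
#' `[-site_shift/2, +site_shift/2]` across sites, so the cohort mean is
#' unaffected). Signals are drawn i.i.d. in time from a zero-mean
#' multivariate normal with the subject's group/site correlation matrix.
#'
#' Defaults are the desk-scale geometry (20 ROIs, 200 time points, 100
#' subjects per group, 4 sites, planted effect 0.3) that trains in well under
#' a minute on one CPU; the 160-ROI paper-scale geometry is available by
#' setting `n_rois = 160`.
#'
#' @param n_per_group Subjects per group (cases and controls each).
#' @param n_rois Number of ROIs.
#' @param T_len Time points per subject.
#' @param n_blocks Number of correlation blocks (communities).
#' @param base_within_r,base_between_r Baseline within-/between-block
#'   correlations, in (-1, 1).
#' @param effect_delta Added to within-block correlations of the case (MDD)
#'   group.
#' @param site_count Number of acquisition sites; subjects are dealt to sites
#'   round-robin within each group.
#' @param site_shift Total spread of the per-site global correlation offset.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   spec.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_per_group = 100L, n_rois = 20L,
                                  T_len = 200L, n_blocks = 4L,
                                  base_within_r = 0.4, base_between_r = 0.1,
                                  effect_delta = 0.3, site_count = 4L,
                                  site_shift = 0.1, seed = 1L) {
  stopifnot(n_per_group >= 1, n_rois >= 2, T_len >= 3, n_blocks >= 1,
            n_blocks <= n_rois,
            abs(base_within_r) < 1, abs(base_between_r) < 1,
            site_count >= 1, site_shift >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois), T_len = as.integer(T_len),
                 n_blocks = as.integer(n_blocks),
                 base_within_r = base_within_r,
                 base_between_r = base_between_r,
                 effect_delta = effect_delta,
                 site_count = as.integer(site_count),
                 site_shift = site_shift, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# block id of each ROI, blocks as equal as possible
block_ids <- function(n_rois, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_rois))
}

site_offset <- function(spec, site_index) {
  s <- spec$site_count
  if (s == 1 || spec$site_shift == 0) return(0)
  spec$site_shift * ((site_index - 1) / (s - 1) - 0.5)
}

# Project a symmetric matrix to the nearest PSD correlation matrix:
# clip negative eigenvalues at zero, rebuild, renormalize to unit diagonal.
nearest_psd_correlation <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= -1e-12)) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(e$values, 0)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(r)
  if (any(d <= 0)) stop("correlation matrix not repairable to PSD", call. = FALSE)
  r <- r / sqrt(d %o% d)
  (r + t(r)) / 2
}

#' Group/site correlation matrix of the generator
#'
#' Builds the block-structured correlation matrix for one group at one site:
#' `base_within_r` within blocks (+ `effect_delta` for cases),
#' `base_between_r` across blocks, plus the site's global offset, repaired to
#' the nearest positive-semidefinite correlation matrix (eigenvalue clipping
#' followed by renormalization to unit diagonal).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param group `"case"` (MDD) or `"control"` (NC).
#' @param site Site index in `1..site_count`.
#' @return Symmetric PSD correlation matrix, `n_rois x n_rois`.
#' @export
build_group_covariance <- function(spec, group = c("case", "control"),
                                   site = 1L) {
  group <- match.arg(group)
  stopifnot(site >= 1, site <= spec$site_count)
  blk <- block_ids(spec$n_rois, spec$n_blocks)
  within <- outer(blk, blk, "==")
  r <- ifelse(within, spec$base_within_r, spec$base_between_r)
  if (group == "case") r[within] <- r[within] + spec$effect_delta
  r <- r + site_offset(spec, site)
  if (any(abs(r[upper.tri(r)]) >= 1)) {
    stop("requested correlations leave (-1, 1); reduce effect_delta/site_shift",
         call. = FALSE)
  }
  diag(r) <- 1
  nearest_psd_correlation(r)
}

rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  ch <- tryCatch(chol(sigma),
                 error = function(e) chol(sigma + diag(1e-8, p)))
  matrix(stats::rnorm(n * p), n, p) %*% ch
}

#' Generate a synthetic two-group multi-site cohort
#'
#' Draws every subject's `n_rois x T` signal matrix from the multivariate
#' normal implied by its group/site correlation matrix. Deterministic under
#' `spec$seed`. Subject ids are `case_001`, `control_001`, ...; labels are
#' `MDD` for cases and `NC` for controls; sites are `S1..S<site_count>`
#' assigned round-robin within each group so every site holds both classes.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List of [roi_time_series()] objects, cases first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  sigmas <- list(
    case = lapply(seq_len(spec$site_count), function(s)
      build_group_covariance(spec, "case", s)),
    control = lapply(seq_len(spec$site_count), function(s)
      build_group_covariance(spec, "control", s)))
  out <- vector("list", 2L * spec$n_per_group)
  idx <- 1L
  for (group in c("case", "control")) {
    label <- if (group == "case") "MDD" else "NC"
    for (i in seq_len(spec$n_per_group)) {
      s <- ((i - 1L) %% spec$site_count) + 1L
      sig <- t(rmvnorm_chol(spec$T_len, sigmas[[group]][[s]]))
      out[[idx]] <- roi_time_series(
        sig, subject_id = sprintf("%s_%03d", group, i), label = label,
        site_id = paste0("S", s))
      idx <- idx + 1L
    }
  }
  out
}

#' Build classifier-ready graphs from a cohort of time series
#'
#' Convenience wrapper running [pearson_fc()], [threshold_binarize()] and
#' [build_graph()] over a whole cohort.
#'
#' @param cohort List of `roi_ts` objects.
#' @param tau Binarization threshold.
#' @param absolute,features Passed through to [threshold_binarize()] and
#'   [build_graph()].
#' @return List of `brain_graph` objects.
#' @export
cohort_to_graphs <- function(cohort, tau = 0.3, absolute = FALSE,
                             features = "weighted") {
  lapply(cohort, function(ts) {
    fc <- pearson_fc(ts)
    build_graph(fc, threshold_binarize(fc, tau, absolute = absolute),
                features = features)
  })
}
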