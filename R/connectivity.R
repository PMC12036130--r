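#' Generate per-subject Fisher-z connectivity with block structure
#'
#' Simulates subjects-by-pairs Fisher-z connectivity directly from the block
#' model the enrichment analysis assumes: each ROI pair has a population mean
#' (strong within-network, weak between-network, near-zero for the configured
#' weak blocks such as SAL-Vis), each subject carries a shared random effect
#' per network-pair block (within-block covariance) plus independent
#' pair-level noise. An optional coupling adds
#' \code{slope * (behavior - mean(behavior))} to the target block's mean,
#' linear in the behavior score; a slope of 0 gives an exchangeable null.
#'
#' @param subjects,behaviors Tables from \code{\link{gen_cohort}} (rows
#'   aligned by \code{subject_id}).
#' @param parcellation A \emph{filtered} parcellation
#'   (\code{\link{filter_parcellation}}); unassigned or QC-failing ROIs are an
#'   error.
#' @param cfg A \code{\link{sim_config}}; the coupling is taken from
#'   \code{cfg$coupling}.
#' @param seed Integer seed (default \code{cfg$rng_seed}); \code{NULL} uses
#'   the ambient RNG stream.
#' @return Numeric matrix, subjects x pairs, of Fisher-z connectivity.
#'   Row names are subject ids, column names \code{"roi_i:roi_j"} in canonical
#'   pair order; attribute \code{"pair_index"} holds the
#'   \code{\link{pair_index}} table. Pearson correlations are
#'   \code{tanh()} of the values (unit diagonal implied).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 20)
#' parc <- filter_parcellation(gen_parcellation(40, seed = 1))
#' coh <- gen_cohort(cfg, seed = 1)
#' fc <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg, seed = 1)
#' dim(fc)
gen_connectivity <- function(subjects, behaviors, parcellation,
                             cfg = sim_config(), seed = cfg$rng_seed) {
  .validate_sim_config(cfg)
  if (any(!parcellation$qc_pass) || any(parcellation$network == .unassigned))
    stop("parcellation must be filtered before simulating connectivity ",
         "(see filter_parcellation)")
  stopifnot(identical(subjects$subject_id, behaviors$subject_id))
  n <- nrow(subjects)
  pidx <- pair_index(parcellation)
  P <- nrow(pidx)

  # block key per pair: unordered network pair in canonical order
  nets <- .network_order(unique(parcellation$network))
  a <- match(pidx$net_i, nets)
  b <- match(pidx$net_j, nets)
  block_key <- paste(pmin(a, b), pmax(a, b))
  block_id <- match(block_key, unique(block_key))
  n_blocks <- max(block_id)

  mu <- ifelse(pidx$net_i == pidx$net_j, cfg$mu_within, cfg$mu_between)
  for (wp in cfg$weak_pairs) {
    hitp <- (pidx$net_i == wp[1] & pidx$net_j == wp[2]) |
      (pidx$net_i == wp[2] & pidx$net_j == wp[1])
    mu[hitp] <- cfg$mu_weak
  }

  target <- NULL
  slope <- 0
  if (!is.null(cfg$coupling) && cfg$coupling$slope != 0) {
    cp <- cfg$coupling
    if (!all(cp$networks %in% parcellation$network))
      stop("coupling target is not a valid network pair for this ",
           "parcellation: ", paste(cp$networks, collapse = "-"))
    if (!cp$behavior %in% names(behaviors)[-1])
      stop("unknown coupling behavior: ", cp$behavior)
    target <- (pidx$net_i == cp$networks[1] & pidx$net_j == cp$networks[2]) |
      (pidx$net_i == cp$networks[2] & pidx$net_j == cp$networks[1])
    if (!any(target))
      stop("coupling target block ", paste(cp$networks, collapse = "-"),
           " contains no ROI pairs")
    sgn <- if (is.null(cp$sign)) 1 else cp$sign
    slope <- cp$slope * sgn
  }

  .with_seed(seed, {
    z <- matrix(stats::rnorm(n * P, sd = cfg$sigma_pair), n, P)
    if (cfg$tau_block > 0) {
      beff <- matrix(stats::rnorm(n * n_blocks, sd = cfg$tau_block),
                     n, n_blocks)
      z <- z + beff[, block_id, drop = FALSE]
    }
    z <- sweep(z, 2L, mu, "+")
    if (!is.null(target)) {
      beh <- as.numeric(behaviors[[cfg$coupling$behavior]])
      z[, target] <- z[, target] + (beh - mean(beh)) * slope
    }
    dimnames(z) <- list(subjects$subject_id, pidx$name)
    attr(z, "pair_index") <- pidx
    z
  })
}

#' Calibrate the planted-coupling slope to a target screening effect size
#'
#' Chooses the coupling slope so that, under the generator's noise model, the
#' mean absolute screening t-statistic in the target block equals
#' \code{target_mean_abs_t}. The per-pair noncentrality delta solves
#' \code{E|N(delta, 1)| = target}, and the slope converts delta to Fisher-z
#' units through the design-based standard error of the coupled behavior's
#' coefficient: \code{slope = delta * sigma_tot * sqrt((X'X)^{-1}[j, j])},
#' with \code{sigma_tot^2 = tau_block^2 + sigma_pair^2}.
#'
#' A target of about 1 gives a subtle effect (the null expectation of |t| is
#' already ~0.8); a target of about 1.5 reproduces the effect scale at which
#' roughly a quarter of block members clear a two-sided 5% screen.
#'
#' @param design A \code{\link{build_design}} object for the cohort.
#' @param cfg A \code{\link{sim_config}} supplying the noise SDs.
#' @param target_mean_abs_t Desired mean |t| within the coupled block.
#' @param behavior Which behavior's design column the coupling acts on.
#' @return The slope (Fisher-z units per unit of centered behavior score).
#' @export
calibrate_slope <- function(design, cfg = sim_config(),
                            target_mean_abs_t = 1,
                            behavior = "SA") {
  stopifnot(inherits(design, "fcea_design"))
  e_abs <- function(d) d * (2 * stats::pnorm(d) - 1) + 2 * stats::dnorm(d)
  if (target_mean_abs_t <= e_abs(0))
    stop("target_mean_abs_t must exceed the null expectation ",
         round(e_abs(0), 3))
  delta <- stats::uniroot(function(d) e_abs(d) - target_mean_abs_t,
                          c(0, 50))$root
  j <- match(behavior, colnames(design$X))
  if (is.na(j)) stop("behavior ", behavior, " not in design columns")
  sigma_tot <- sqrt(cfg$tau_block^2 + cfg$sigma_pair^2)
  delta * sigma_tot * sqrt(design$XtXinv[j, j])
}

#' Reconstruct a symmetric ROI x ROI matrix from a pair vector
#'
#' Inverse of the canonical upper-triangle vectorization: fills a symmetric
#' matrix from per-pair values in \code{\link{pair_index}} order.
#'
#' @param values Numeric vector of length R(R-1)/2 in canonical pair order.
#' @param parcellation The (filtered) parcellation defining ROI order.
#' @param diag_value Value for the diagonal (default \code{NA}).
#' @return R x R symmetric matrix with ROI ids as dimnames.
#' @export
pairs_to_matrix <- function(values, parcellation, diag_value = NA_real_) {
  R <- nrow(parcellation)
  stopifnot(length(values) == R * (R - 1) / 2)
  m <- matrix(diag_value, R, R,
              dimnames = list(parcellation$roi_id, parcellation$roi_id))
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Extract the canonical pair vector from a symmetric matrix
#'
#' @param m Symmetric ROI x ROI matrix.
#' @return Upper-triangle values in canonical (column-major) pair order.
#' @export
matrix_to_pairs <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}
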