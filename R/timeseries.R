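#' Generate synthetic ROI time series with motion and nuisance structure
#'
#' Simulates, for each subject, an ROI time-series matrix whose empirical
#' correlations converge (in frames) to a block-structured network model
#' consistent with \code{\link{gen_connectivity}}: ROIs load on correlated
#' network factors, giving within-network correlation \code{mu_within} and
#' between-network correlation \code{mu_between} (weak blocks use
#' \code{mu_weak}). Nine nuisance channels (CSF, white matter, global signal,
#' six motion parameters) are simulated as smooth AR(1) series and injected
#' into the ROI series with random loadings scaled by
#' \code{cfg$artifact_strength}, so that nuisance regression can remove them.
#' Framewise displacement is a non-negative baseline with occasional
#' high-motion spikes (rate \code{cfg$fd_spike_rate}).
#'
#' @param subjects Subject table (\code{\link{gen_cohort}}).
#' @param parcellation Filtered parcellation.
#' @param cfg A \code{\link{sim_config}} (uses \code{tr},
#'   \code{duration_min}, the connectivity means, \code{fd_spike_rate},
#'   \code{artifact_strength}).
#' @param seed Integer seed (default \code{cfg$rng_seed}).
#' @param frames Number of frames; default
#'   \code{round(duration_min * 60 / tr)}.
#' @return List of per-subject objects of class \code{"fcea_ts"}: each a list
#'   with \code{subject_id}, \code{tr} (seconds), \code{frames},
#'   \code{series} (frames x ROI matrix, ROI ids as column names), \code{fd}
#'   (per-frame framewise displacement, mm) and \code{nuisance} (frames x 9
#'   matrix: \code{csf}, \code{wm}, \code{global}, \code{mot_x}, \code{mot_y},
#'   \code{mot_z}, \code{mot_pitch}, \code{mot_yaw}, \code{mot_roll}).
#' @export
gen_timeseries <- function(subjects, parcellation, cfg = sim_config(),
                           seed = cfg$rng_seed, frames = NULL) {
  .validate_sim_config(cfg)
  if (cfg$tr <= 0) stop("tr must be positive")
  if (is.null(frames)) frames <- as.integer(round(cfg$duration_min * 60 / cfg$tr))
  if (frames < 2L) stop("need at least 2 frames")
  R <- nrow(parcellation)
  nets <- .network_order(unique(parcellation$network))
  G <- length(nets)
  gidx <- match(parcellation$network, nets)

  # factor model: x_r = sqrt(a) f_g(r) + sqrt(1-a) e_r gives within-network
  # correlation a and between-network correlation a * phi_gh
  a <- cfg$mu_within
  phi <- matrix(cfg$mu_between / a, G, G)
  diag(phi) <- 1
  for (wp in cfg$weak_pairs) {
    gi <- match(wp[1], nets); gj <- match(wp[2], nets)
    if (!is.na(gi) && !is.na(gj)) phi[gi, gj] <- phi[gj, gi] <- cfg$mu_weak / a
  }
  Lphi <- tryCatch(chol(phi), error = function(e)
    stop("network factor correlation matrix is not positive definite; ",
         "reduce mu_between relative to mu_within"))

  nuis_names <- c("csf", "wm", "global", "mot_x", "mot_y", "mot_z",
                  "mot_pitch", "mot_yaw", "mot_roll")

  ar1 <- function(n, rho, sd = 1) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, sd = sd)
    innov <- stats::rnorm(n - 1, sd = sd * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
    x
  }

  .with_seed(seed, {
    lapply(seq_len(nrow(subjects)), function(s) {
      f <- matrix(stats::rnorm(frames * G), frames, G) %*% Lphi
      e <- matrix(stats::rnorm(frames * R), frames, R)
      x <- sqrt(a) * f[, gidx, drop = FALSE] + sqrt(1 - a) * e

      nuis <- vapply(seq_along(nuis_names), function(k) ar1(frames, 0.8),
                     numeric(frames))
      colnames(nuis) <- nuis_names
      if (cfg$artifact_strength > 0) {
        load <- matrix(stats::rnorm(length(nuis_names) * R,
                                    sd = cfg$artifact_strength),
                       length(nuis_names), R)
        x <- x + nuis %*% load
      }

      fd <- abs(stats::rnorm(frames, 0.06, 0.03))
      spikes <- stats::runif(frames) < cfg$fd_spike_rate
      fd[spikes] <- stats::runif(sum(spikes), 0.3, 1.2)

      colnames(x) <- parcellation$roi_id
      structure(list(subject_id = subjects$subject_id[s], tr = cfg$tr,
                     frames = frames, series = x, fd = fd, nuisance = nuis),
                class = "fcea_ts")
    })
  })
}
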