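#' Simulation configuration for synthetic cohorts
#'
#' Collects the parameters of the synthetic brain-behavior cohort generator.
#' Defaults emulate the structure of a multi-site familial-likelihood study of
#' school-age children: 97 subjects across 4 sites, about two thirds at high
#' familial likelihood (HL), floor-inflated ordinal severity scores for social
#' affect (SA) and restricted/repetitive behavior (RRB), four continuous
#' instrument scores (GAD, CONP, LIMB, DAS), and block-structured Fisher-z
#' connectivity with strong within-network and weak between-network coupling,
#' the salience-visual (SAL-Vis) block being near zero on average.
#'
#' @param n_subjects Number of subjects.
#' @param site_proportions Named numeric vector of site sampling proportions
#'   (sites \code{A}..\code{D} by default; 34/23/23/17 out of 97).
#' @param hl_fraction Fraction of subjects at high familial likelihood.
#' @param male_fraction Fraction of male subjects (55/97 by default).
#' @param asd_rate_hl,asd_rate_ll Diagnosis rates within the HL and LL groups
#'   (11/63 and 4/34 by default).
#' @param age_range,age_mean,age_sd Age-at-scan distribution (years): normal,
#'   truncated to \code{age_range}.
#' @param sleeper_count Number of subjects flagged as having slept or been
#'   drowsy during the scan (drawn among non-diagnosed subjects); default
#'   \code{min(8, n_subjects)}.
#' @param medication_count Number of subjects flagged as taking medication on
#'   scan day; default \code{min(12, n_subjects)}.
#' @param sa_floor_probability,rrb_floor_probability Probability mass at the
#'   floor score of 1 for the SA and RRB calibrated severity scores (1-10).
#' @param severity_decay Geometric decay of the above-floor severity mass over
#'   scores 2..10; smaller values concentrate mass near the floor.
#' @param behavior_cor Latent exchangeable correlation of the Gaussian copula
#'   linking the six behaviors.
#' @param mu_within,mu_between Population mean Fisher-z connectivity for
#'   within-network and between-network ROI pairs.
#' @param weak_pairs List of 2-vectors of network labels whose between-network
#'   block mean is \code{mu_weak} instead of \code{mu_between} (default the
#'   SAL-Vis block).
#' @param mu_weak Population mean Fisher-z connectivity of the weak blocks.
#' @param tau_block SD of the subject-by-block random effect (shared by all
#'   pairs of a network-pair block within a subject; the within-block
#'   covariance of the generator).
#' @param sigma_pair SD of the independent pair-level noise.
#' @param coupling \code{NULL} for a null cohort, or a list with elements
#'   \code{networks} (2-vector of network labels), \code{behavior} (one of
#'   \code{"SA"}, \code{"RRB"}, \code{"GAD"}, \code{"CONP"}, \code{"LIMB"},
#'   \code{"DAS"}), \code{slope} (Fisher-z units per centered score unit) and
#'   optionally \code{sign} (+1/-1 multiplier, default +1). A slope of 0 is an
#'   exact null.
#' @param tr Repetition time in seconds for the time-series path.
#' @param duration_min Acquisition duration in minutes.
#' @param fd_spike_rate Per-frame probability of a high-motion spike in
#'   simulated framewise displacement.
#' @param artifact_strength SD multiplier of the nuisance-artifact loadings
#'   injected into simulated ROI time series.
#' @param rng_seed Default seed used by the generator functions when their
#'   \code{seed} argument is missing.
#' @return A list of class \code{"fcea_sim_config"}.
#' @export
sim_config <- function(n_subjects = 97L,
                       site_proportions = c(A = 34, B = 23, C = 23, D = 17) / 97,
                       hl_fraction = 63 / 97,
                       male_fraction = 55 / 97,
                       asd_rate_hl = 11 / 63,
                       asd_rate_ll = 4 / 34,
                       age_range = c(8.1, 12.0),
                       age_mean = 10.1,
                       age_sd = 1.0,
                       sleeper_count = NULL,
                       medication_count = NULL,
                       sa_floor_probability = 0.60,
                       rrb_floor_probability = 0.55,
                       severity_decay = 0.75,
                       behavior_cor = 0.30,
                       mu_within = 0.30,
                       mu_between = 0.05,
                       weak_pairs = list(c("SAL", "Vis")),
                       mu_weak = 0.02,
                       tau_block = 0.02,
                       sigma_pair = 0.18,
                       coupling = NULL,
                       tr = 2.0,
                       duration_min = 11.2,
                       fd_spike_rate = 0.08,
                       artifact_strength = 0.4,
                       rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  # study defaults (8 sleepers, 12 medicated of 97) shrink with small cohorts
  if (is.null(sleeper_count)) sleeper_count <- min(8L, n_subjects)
  if (is.null(medication_count)) medication_count <- min(12L, n_subjects)
  cfg <- list(n_subjects = n_subjects,
              site_proportions = site_proportions,
              hl_fraction = hl_fraction, male_fraction = male_fraction,
              asd_rate_hl = asd_rate_hl, asd_rate_ll = asd_rate_ll,
              age_range = age_range, age_mean = age_mean, age_sd = age_sd,
              sleeper_count = as.integer(sleeper_count),
              medication_count = as.integer(medication_count),
              sa_floor_probability = sa_floor_probability,
              rrb_floor_probability = rrb_floor_probability,
              severity_decay = severity_decay,
              behavior_cor = behavior_cor,
              mu_within = mu_within, mu_between = mu_between,
              weak_pairs = weak_pairs, mu_weak = mu_weak,
              tau_block = tau_block, sigma_pair = sigma_pair,
              coupling = coupling,
              tr = tr, duration_min = duration_min,
              fd_spike_rate = fd_spike_rate,
              artifact_strength = artifact_strength,
              rng_seed = rng_seed)
  .validate_sim_config(cfg)
  structure(cfg, class = "fcea_sim_config")
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$hl_fraction, cfg$male_fraction, cfg$asd_rate_hl,
             cfg$asd_rate_ll, cfg$sa_floor_probability,
             cfg$rrb_floor_probability, cfg$site_proportions)
  if (any(probs < 0 | probs > 1))
    stop("probabilities in sim_config must lie in [0, 1]")
  if (abs(sum(cfg$site_proportions) - 1) > 1e-8)
    stop("site_proportions must sum to 1")
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive")
  if (cfg$sleeper_count > cfg$n_subjects)
    stop("sleeper_count exceeds n_subjects")
  if (cfg$tau_block < 0 || cfg$sigma_pair <= 0)
    stop("noise SDs must be positive (tau_block may be zero)")
  if (!is.null(cfg$coupling)) {
    cp <- cfg$coupling
    if (!is.list(cp) || is.null(cp$networks) || is.null(cp$behavior) ||
        is.null(cp$slope) || length(cp$networks) != 2L)
      stop("coupling must be a list with networks (length 2), behavior, slope")
  }
  invisible(cfg)
}

# run expr under a temporary seed, restoring the ambient RNG state;
# seed = NULL draws from the ambient stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  force(expr)
}

# floor-inflated ordinal severity marginal on 1..10
.severity_probs <- function(floor_p, decay) {
  tail <- decay^(0:8)
  c(floor_p, (1 - floor_p) * tail / sum(tail))
}

#' Generate a synthetic subject manifest and behavior table
#'
#' Draws subject records (site, sex, age, familial-likelihood group,
#' diagnosis, sleep/medication flags) and six behavioral scores via a Gaussian
#' copula: the SA and RRB calibrated severity scores use a floor-inflated
#' ordinal marginal on 1..10 (most subjects at the floor score of 1, a tail
#' reaching 5 and beyond), the four continuous scores use instrument-like
#' normal scales. Sleep flags are assigned only to subjects without a
#' diagnosis, mirroring the study design the generator emulates.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Integer seed (default \code{cfg$rng_seed}); \code{NULL} uses the
#'   ambient RNG stream.
#' @return List with elements \code{subjects} (one row per subject:
#'   \code{subject_id}, \code{site}, \code{sex}, \code{age}, \code{group},
#'   \code{asd_dx}, \code{sleep_flag}, \code{medication_flag},
#'   \code{motion_excluded}, \code{clinical_excluded},
#'   \code{behavior_complete}) and \code{behaviors} (\code{subject_id},
#'   \code{SA}, \code{RRB}, \code{GAD}, \code{CONP}, \code{LIMB}, \code{DAS}).
#' @export
#' @examples
#' cohort <- gen_cohort(sim_config(n_subjects = 40), seed = 2)
#' table(cohort$behaviors$SA)
gen_cohort <- function(cfg = sim_config(), seed = cfg$rng_seed) {
  .validate_sim_config(cfg)
  n <- cfg$n_subjects
  .with_seed(seed, {
    site <- sample(names(cfg$site_proportions), n, replace = TRUE,
                   prob = cfg$site_proportions)
    group <- ifelse(stats::runif(n) < cfg$hl_fraction, "HL", "LL")
    sex <- ifelse(stats::runif(n) < cfg$male_fraction, "M", "F")
    age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
                     cfg$age_range[1]), cfg$age_range[2])
    asd <- ifelse(group == "HL",
                  stats::runif(n) < cfg$asd_rate_hl,
                  stats::runif(n) < cfg$asd_rate_ll)
    sleep <- rep(FALSE, n)
    pool <- which(!asd)
    if (length(pool) < cfg$sleeper_count) pool <- seq_len(n)
    if (cfg$sleeper_count > 0L)
      sleep[sample(pool, cfg$sleeper_count)] <- TRUE
    med <- rep(FALSE, n)
    if (cfg$medication_count > 0L)
      med[sample(n, min(cfg$medication_count, n))] <- TRUE

    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      site = site, sex = sex, age = round(age, 2), group = group,
      asd_dx = asd, sleep_flag = sleep, medication_flag = med,
      motion_excluded = FALSE, clinical_excluded = FALSE,
      behavior_complete = TRUE, stringsAsFactors = FALSE)

    # Gaussian copula over the six behaviors
    k <- 6L
    Rmat <- matrix(cfg$behavior_cor, k, k); diag(Rmat) <- 1
    L <- chol(Rmat)
    zlat <- matrix(stats::rnorm(n * k), n, k) %*% L
    u <- stats::pnorm(zlat)

    sa_p <- .severity_probs(cfg$sa_floor_probability, cfg$severity_decay)
    rrb_p <- .severity_probs(cfg$rrb_floor_probability, cfg$severity_decay)
    sev <- function(uu, p)
      pmin(findInterval(uu, cumsum(p)) + 1L, length(p))
    behaviors <- data.frame(
      subject_id = subjects$subject_id,
      SA   = sev(u[, 1], sa_p),
      RRB  = sev(u[, 2], rrb_p),
      GAD  = round(50 + 10 * zlat[, 3], 1),
      CONP = round(50 + 10 * zlat[, 4], 1),
      LIMB = round(15 + 5 * zlat[, 5], 1),
      DAS  = round(50 + 10 * zlat[, 6], 1),
      stringsAsFactors = FALSE)

    novar <- names(behaviors)[-1][vapply(behaviors[-1], function(x)
      stats::var(as.numeric(x)) == 0, logical(1))]
    if (length(novar))
      warning("behavior column(s) with zero variance: ",
              paste(novar, collapse = ", "), call. = FALSE)

    list(subjects = subjects, behaviors = behaviors)
  })
}

#' Deterministic subject-QC manifest fixture
#'
#' Builds a 121-subject manifest with the canonical attrition pattern used for
#' exercising subject quality control: 7 subjects excluded for motion, 1 for a
#' clinically abnormal scan, 16 with incomplete behavioral data, and 97 clean
#' records. The fixture is deterministic (no RNG).
#'
#' @param n_total,n_motion,n_clinical,n_incomplete Counts for the manifest;
#'   the defaults encode the 121 = 7 + 1 + 16 + 97 pattern.
#' @return Subject data frame in the format of \code{\link{gen_cohort}}.
#' @export
#' @examples
#' m <- gen_qc_manifest_fixture()
#' nrow(subject_qc_filter(m))  # 97
gen_qc_manifest_fixture <- function(n_total = 121L, n_motion = 7L,
                                    n_clinical = 1L, n_incomplete = 16L) {
  stopifnot(n_motion + n_clinical + n_incomplete <= n_total)
  n <- as.integer(n_total)
  sites <- rep(c("A", "B", "C", "D"), length.out = n)
  subjects <- data.frame(
    subject_id = sprintf("Q%03d", seq_len(n)),
    site = sites,
    sex = rep(c("M", "F"), length.out = n),
    age = round(seq(8.1, 12.0, length.out = n), 2),
    group = rep(c("HL", "HL", "LL"), length.out = n),
    asd_dx = FALSE, sleep_flag = FALSE, medication_flag = FALSE,
    motion_excluded = FALSE, clinical_excluded = FALSE,
    behavior_complete = TRUE, stringsAsFactors = FALSE)
  subjects$motion_excluded[seq_len(n_motion)] <- TRUE
  subjects$clinical_excluded[n_motion + seq_len(n_clinical)] <- TRUE
  subjects$behavior_complete[n_motion + n_clinical + seq_len(n_incomplete)] <- FALSE
  subjects
}

#' Apply subject-level quality control to a manifest
#'
#' Retains subjects that are not motion-excluded, not clinically excluded, and
#' have complete behavioral data; logs the attrition.
#'
#' @param subjects Subject data frame (see \code{\link{gen_cohort}}).
#' @return Filtered subject data frame.
#' @export
subject_qc_filter <- function(subjects) {
  stopifnot(all(c("motion_excluded", "clinical_excluded", "behavior_complete")
                %in% names(subjects)))
  keep <- !subjects$motion_excluded & !subjects$clinical_excluded &
    subjects$behavior_complete
  out <- subjects[keep, , drop = FALSE]
  rownames(out) <- NULL
  message("subject_qc_filter: retained ", nrow(out), " of ", nrow(subjects),
          " subjects (motion ", sum(subjects$motion_excluded),
          ", clinical ", sum(subjects$clinical_excluded),
          ", incomplete behavior ", sum(!subjects$behavior_complete), ")")
  out
}
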