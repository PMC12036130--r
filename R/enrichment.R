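#' Enrichment-analysis configuration
#'
#' Collects the tunable parameters of the network-pair enrichment analysis.
#' Defaults follow the scale such analyses are run at: a 5% screening threshold for
#' over-representation, 250,000 permutations for ORA and max-mean, 25,000 for
#' the compute-heavier GSEA statistic, and a per-test significance level of
#' 0.0005 calibrated to give roughly a 5% experiment-wide false-positive rate
#' over 91 network-pair blocks.
#'
#' @param ora_alpha Two-sided screening significance threshold defining an
#'   ORA exceedance (default 0.05).
#' @param maxmean_variant \code{"efron_tibshirani"} (default): the larger of
#'   the mean positive part and the mean absolute negative part, both over
#'   the full block size; \code{"signed_difference"}: the signed difference
#'   (sum of positives minus sum of absolute negatives) over the block size.
#'   The Efron-Tibshirani form is the default because its permutation null is
#'   positive with median well away from zero (about 0.5 for t screening),
#'   matching reported null envelopes for this statistic, whereas the signed
#'   difference has a symmetric null centered at 0.
#' @param gsea_weight Exponent on the ranked statistic magnitudes in the
#'   GSEA running sum (default 1; 0 gives the unweighted KS statistic).
#' @param B_ora,B_maxmean,B_gsea Permutation counts per statistic.
#' @param alpha_per_test Per-block significance level (default 0.0005).
#' @param permutation_scheme \code{"freedman_lane"} (default): permute
#'   reduced-model residuals with the covariate fit held fixed;
#'   \code{"joint_behavior_shuffle"}: permute the six behavior rows jointly
#'   against fixed connectivity and covariates.
#' @param seed Integer seed for the permutation streams.
#' @return List of class \code{"fcea_ea_config"}.
#' @export
ea_config <- function(ora_alpha = 0.05,
                      maxmean_variant = c("efron_tibshirani", "signed_difference"),
                      gsea_weight = 1,
                      B_ora = 250000L, B_maxmean = 250000L, B_gsea = 25000L,
                      alpha_per_test = 5e-4,
                      permutation_scheme = c("freedman_lane",
                                             "joint_behavior_shuffle"),
                      seed = 1L) {
  maxmean_variant <- match.arg(maxmean_variant)
  permutation_scheme <- match.arg(permutation_scheme)
  if (min(B_ora, B_maxmean, B_gsea) < 1L)
    stop("permutation counts must be at least 1")
  if (ora_alpha <= 0 || ora_alpha >= 1 || alpha_per_test <= 0 ||
      alpha_per_test >= 1)
    stop("significance levels must lie in (0, 1)")
  structure(list(ora_alpha = ora_alpha, maxmean_variant = maxmean_variant,
                 gsea_weight = gsea_weight,
                 B_ora = as.integer(B_ora), B_maxmean = as.integer(B_maxmean),
                 B_gsea = as.integer(B_gsea),
                 alpha_per_test = alpha_per_test,
                 permutation_scheme = permutation_scheme,
                 seed = as.integer(seed)),
            class = "fcea_ea_config")
}

#' Define network-pair blocks over a parcellation
#'
#' Partitions the canonical ROI pairs into network-pair blocks (within-network
#' blocks included): G networks give G(G+1)/2 blocks, e.g. 91 for 13
#' networks. Blocks of networks with a single ROI can be empty; they are kept
#' in the table (k = 0) and skipped by downstream statistics.
#'
#' @param parcellation A filtered parcellation; an unassigned ROI is an error.
#' @return List of class \code{"fcea_blocks"}: \code{blocks} (data frame
#'   \code{block}, \code{net_a}, \code{net_b}, \code{k}), \code{pair_block}
#'   (block id per canonical pair) and \code{idx} (per-block pair indices).
#' @export
#' @examples
#' parc <- filter_parcellation(gen_parcellation(40, seed = 1))
#' bl <- define_blocks(parc)
#' nrow(bl$blocks)  # 91
define_blocks <- function(parcellation) {
  if (any(parcellation$network == .unassigned))
    stop("parcellation contains unassigned ROIs; filter it first")
  pidx <- pair_index(parcellation)
  nets <- .network_order(unique(parcellation$network))
  G <- length(nets)
  a <- pmin(match(pidx$net_i, nets), match(pidx$net_j, nets))
  b <- pmax(match(pidx$net_i, nets), match(pidx$net_j, nets))
  # block id in (a <= b) lexicographic order over the network list:
  # row a holds G - a + 1 blocks, so its offset is (a-1)(G+1) - a(a-1)/2
  block_of <- function(a, b)
    (a - 1L) * (G + 1L) - as.integer(a * (a - 1L) / 2) + b - a + 1L
  pair_block <- block_of(a, b)
  n_blocks <- as.integer(G * (G + 1) / 2)
  ai <- rep(seq_len(G), times = G - seq_len(G) + 1L)
  bi <- unlist(lapply(seq_len(G), function(x) x:G), use.names = FALSE)
  k <- tabulate(pair_block, nbins = n_blocks)
  idx <- split(seq_len(nrow(pidx)), factor(pair_block, levels = seq_len(n_blocks)))
  structure(list(blocks = data.frame(block = seq_len(n_blocks),
                                     net_a = nets[ai], net_b = nets[bi],
                                     k = k, stringsAsFactors = FALSE),
                 pair_block = pair_block,
                 idx = idx,
                 n_pairs = nrow(pidx)),
            class = "fcea_blocks")
}

#' Over-representation proportion for one block
#'
#' Fraction of a block's screening statistics that clear the two-sided
#' \code{alpha} significance threshold for the model's degrees of freedom
#' (t channel: \code{|t| > t_crit(df, alpha/2)}; F channel:
#' \code{F > F_crit(2, df, alpha)}). Its null expectation is \code{alpha}.
#'
#' @param stats All-pair screening statistics (only the block members are
#'   used, but the full vector may be passed).
#' @param members Pair indices of the block.
#' @param alpha Screening threshold (default 0.05).
#' @param df Residual (denominator) degrees of freedom.
#' @param channel \code{"t"} or \code{"f"}.
#' @return Proportion in [0, 1].
#' @export
ora_stat <- function(stats, members, alpha = 0.05, df,
                     channel = c("t", "f")) {
  channel <- match.arg(channel)
  if (length(members) == 0L) stop("empty block")
  s <- stats[members]
  crit <- .ora_crit(alpha, df, channel)
  if (channel == "t") mean(abs(s) > crit) else mean(s > crit)
}

.ora_crit <- function(alpha, df, channel) {
  if (channel == "t") stats::qt(1 - alpha / 2, df)
  else stats::qf(1 - alpha, 2, df)
}

#' Analytic hypergeometric p-value for block over-representation
#'
#' Upper-tail hypergeometric probability of observing at least the block's
#' exceedance count, given the brain-wide exceedance total, the block size
#' and the total pair count. A fast analytic cross-check; permutation
#' p-values are the primary inference.
#'
#' @inheritParams ora_stat
#' @return Upper-tail p-value in (0, 1].
#' @export
ora_hypergeom_p <- function(stats, members, alpha = 0.05, df,
                            channel = c("t", "f")) {
  channel <- match.arg(channel)
  if (length(members) == 0L) stop("empty block")
  crit <- .ora_crit(alpha, df, channel)
  ex <- if (channel == "t") abs(stats) > crit else stats > crit
  m <- sum(ex)
  q <- sum(ex[members])
  stats::phyper(q - 1, m, length(stats) - m, length(members),
                lower.tail = FALSE)
}

#' Max-mean statistic for one block
#'
#' Directional block summary of signed t statistics. The default
#' Efron-Tibshirani form is
#' \code{max(sum(pos)/k, sum(|neg|)/k)} over the block size k; the
#' \code{"signed_difference"} variant is the signed difference
#' \code{(sum(pos) - sum(|neg|))/k}. Directional, so only defined for the
#' t channels; requesting it for the F channel is an error.
#'
#' @inheritParams ora_stat
#' @param variant \code{"efron_tibshirani"} or \code{"signed_difference"}.
#' @return The block statistic (non-negative for the default variant).
#' @export
#' @examples
#' maxmean_stat(c(2, -1, 1, -4), 1:4)                    # 1.25
#' maxmean_stat(c(2, -1, 1, -4), 1:4, "signed_difference")   # -0.5
maxmean_stat <- function(stats, members,
                         variant = c("efron_tibshirani", "signed_difference"),
                         channel = "t") {
  variant <- match.arg(variant)
  if (channel != "t")
    stop("max-mean is a directional statistic and is undefined for the F ",
         "screening channel")
  if (length(members) == 0L) stop("empty block")
  s <- stats[members]
  k <- length(s)
  pos <- sum(pmax(s, 0)) / k
  neg <- sum(pmax(-s, 0)) / k
  if (variant == "efron_tibshirani") max(pos, neg) else pos - neg
}

#' GSEA-style running-sum enrichment score for one block
#'
#' Ranks all pairs by decreasing statistic magnitude (t channels: |t|;
#' F channel: F itself), walks the ranking incrementing by the block member's
#' weight fraction \code{|s|^weight / sum_block |s|^weight} at members and
#' decrementing by \code{1/(P - k)} elsewhere, and returns the maximum
#' positive deviation of the running sum (in [0, 1]). \code{weight = 0}
#' reduces to the unweighted Kolmogorov-Smirnov statistic.
#'
#' @inheritParams ora_stat
#' @param weight Exponent on the statistic magnitudes (default 1).
#' @return Enrichment score in [0, 1].
#' @export
gsea_stat <- function(stats, members, weight = 1, channel = c("t", "f")) {
  channel <- match.arg(channel)
  if (length(members) == 0L) stop("empty block")
  key <- if (channel == "t") abs(stats) else stats
  if (all(key == 0)) stop("all screening statistics are zero; ",
                          "GSEA weights are undefined")
  P <- length(stats)
  k <- length(members)
  if (k >= P) stop("block must be a strict subset of all pairs")
  rk <- integer(P)
  rk[order(key, decreasing = TRUE)] <- seq_len(P)
  .es_from_ranks(rk[members], key[members]^weight, P, k)
}

# ES from the member ranks: the running sum attains its maximum immediately
# after a member increment, so only member positions need inspection.
.es_from_ranks <- function(member_ranks, w, P, k) {
  o <- order(member_ranks)
  r <- member_ranks[o]
  w <- w[o]
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  max(0, max(cumsum(w) / sw - (r - seq_len(k)) / (P - k)))
}

#' Permutation p-value (add-one estimator)
#'
#' \code{p = (#\{null >= observed\} + 1) / (B + 1)}, upper tail.
#'
#' @param observed Observed statistic.
#' @param null_samples Vector of null statistics.
#' @return p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, null_samples) {
  (sum(null_samples >= observed) + 1) / (length(null_samples) + 1)
}

# block statistics for one channel's all-pair statistic vector.
# Returns a list keyed by statistic, each a vector over all blocks
# (NA for empty blocks).
.block_stats_all <- function(s, chan_type, blocks, cfg, df, statistics) {
  nb <- nrow(blocks$blocks)
  kvec <- blocks$blocks$k
  nonempty <- which(kvec > 0L)
  out <- list()
  if ("ora" %in% statistics) {
    crit <- .ora_crit(cfg$ora_alpha, df, chan_type)
    ex <- if (chan_type == "t") abs(s) > crit else s > crit
    cnt <- tabulate(blocks$pair_block[ex], nbins = nb)
    ora <- rep(NA_real_, nb)
    ora[nonempty] <- cnt[nonempty] / kvec[nonempty]
    out$ora <- ora
  }
  if ("maxmean" %in% statistics && chan_type == "t") {
    sp <- s; sp[sp < 0] <- 0
    sn <- -s; sn[sn < 0] <- 0
    gs <- rowsum(cbind(sp, sn), blocks$pair_block)
    gid <- as.integer(rownames(gs))
    mm <- rep(NA_real_, nb)
    if (cfg$maxmean_variant == "efron_tibshirani")
      mm[gid] <- pmax(gs[, 1], gs[, 2]) / kvec[gid]
    else
      mm[gid] <- (gs[, 1] - gs[, 2]) / kvec[gid]
    out$maxmean <- mm
  }
  if ("gsea" %in% statistics) {
    key <- if (chan_type == "t") abs(s) else s
    P <- length(s)
    rk <- integer(P)
    rk[order(key, decreasing = TRUE, method = "radix")] <- seq_len(P)
    aw <- if (cfg$gsea_weight == 1) key else key^cfg$gsea_weight
    # one pass over all blocks: sort pairs by (block, rank), then the
    # running-sum deviation for every block is a grouped cumsum
    o <- order(blocks$pair_block, rk, method = "radix")
    gsz <- kvec[nonempty]
    rr <- rk[o]
    ww <- aw[o]
    ends <- cumsum(gsz)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    cs <- cumsum(ww)
    base <- c(0, cs[ends[-length(ends)]])
    cw <- cs - rep(base, gsz)
    sw <- cs[ends] - base
    dev <- cw / rep(sw, gsz) -
      (rr - sequence(gsz)) / (P - rep(gsz, gsz))
    tmp <- vapply(seq_along(gsz), function(g) {
      d <- dev[starts[g]:ends[g]]
      max(0, max(d))
    }, numeric(1))
    tmp[sw == 0 | gsz >= P] <- NA_real_
    es <- rep(NA_real_, nb)
    es[nonempty] <- tmp
    out$gsea <- es
  }
  out
}

.chan_type <- function(channel) if (channel == "f_joint") "f" else "t"

# statistics applicable to a channel
.stats_for_channel <- function(channel, statistics) {
  if (channel == "f_joint") setdiff(statistics, "maxmean") else statistics
}

#' Permutation null samples for the block statistics
#'
#' Draws B subject-level relabelings; within each replicate the \emph{same}
#' relabeling is applied brain-wide, all ROI pairs are re-screened under it,
#' and every requested block statistic is evaluated, so the inter-pair
#' correlation structure is preserved in the null. Two schemes are supported:
#' \describe{
#'   \item{freedman_lane}{(default) the connectivity is decomposed into the
#'     reduced-model (covariates-only) fit plus residuals; the residual rows
#'     are permuted and the full model refitted on the reconstructed data.}
#'   \item{joint_behavior_shuffle}{the six behavior rows of the design are
#'     permuted jointly against fixed connectivity and covariates.}
#' }
#'
#' @param fc Subjects x pairs connectivity matrix.
#' @param design A \code{\link{build_design}} object.
#' @param blocks A \code{\link{define_blocks}} object.
#' @param cfg An \code{\link{ea_config}}.
#' @param B Number of permutations.
#' @param channels Subset of \code{c("t_sa", "t_rrb", "f_joint")}.
#' @param statistics Subset of \code{c("ora", "maxmean", "gsea")}
#'   (max-mean is skipped on the F channel).
#' @param seed Seed for the permutation stream (default \code{cfg$seed});
#'   \code{NULL} uses the ambient RNG stream.
#' @param record_indices Keep the permutation index matrix as attribute
#'   \code{"perm_indices"} (B x n; intended for audits at small B).
#' @return Nested list \code{nulls[[channel]][[statistic]]}: a B x n_blocks
#'   matrix of null block statistics.
#' @export
permute_null <- function(fc, design, blocks, cfg = ea_config(), B,
                         channels = c("t_sa", "t_rrb", "f_joint"),
                         statistics = c("ora", "maxmean", "gsea"),
                         seed = cfg$seed, record_indices = FALSE) {
  stopifnot(inherits(design, "fcea_design"), inherits(blocks, "fcea_blocks"))
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  channels <- match.arg(channels, several.ok = TRUE)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (identical(channels, "f_joint") && identical(statistics, "maxmean"))
    stop("max-mean cannot be computed for the F screening channel")
  if (ncol(fc) != blocks$n_pairs)
    stop("fc has ", ncol(fc), " pairs but blocks expect ", blocks$n_pairs)
  n <- design$n
  df <- design$residual_df
  nb <- nrow(blocks$blocks)

  # one subject relabeling per replicate, shared by all statistics/channels
  perms <- .with_seed(seed, t(vapply(seq_len(B), function(b) sample.int(n),
                                     integer(n))))

  if (cfg$permutation_scheme == "freedman_lane") {
    W <- design$X[, -design$idx_test, drop = FALSE]
    qw <- qr(W)
    resW <- fc - qr.fitted(qw, fc)
    raw <- .perm_engine_fl(
      resW, colSums(resW^2), design$Q, design$R,
      design$XtXinv[design$idx_test[1], design$idx_test[1]],
      design$XtXinv[design$idx_test[2], design$idx_test[2]],
      df, perms, blocks$pair_block, nb, as.numeric(blocks$blocks$k),
      "t_sa" %in% channels, "t_rrb" %in% channels, "f_joint" %in% channels,
      "ora" %in% statistics, "maxmean" %in% statistics,
      "gsea" %in% statistics,
      .ora_crit(cfg$ora_alpha, df, "t"), .ora_crit(cfg$ora_alpha, df, "f"),
      cfg$maxmean_variant == "efron_tibshirani", cfg$gsea_weight)
    nulls <- lapply(channels, function(ch) {
      st_ch <- .stats_for_channel(ch, statistics)
      stats::setNames(lapply(st_ch, function(nm) raw[[paste0(ch, ".", nm)]]),
                      st_ch)
    })
    names(nulls) <- channels
  } else {
    beh_cols <- match(c("GAD", "CONP", "LIMB", "DAS", "SA", "RRB"),
                      design$columns)
    beh_cols <- beh_cols[!is.na(beh_cols)]
    nulls <- lapply(channels, function(ch)
      stats::setNames(lapply(.stats_for_channel(ch, statistics), function(st)
        matrix(NA_real_, B, nb)), .stats_for_channel(ch, statistics)))
    names(nulls) <- channels
    for (b in seq_len(B)) {
      Xs <- design$X
      Xs[, beh_cols] <- Xs[perms[b, ], beh_cols]
      st <- .screen_stats(fc, .redesign(design, Xs))
      for (ch in channels) {
        bs <- .block_stats_all(st[[ch]], .chan_type(ch), blocks, cfg, df,
                               .stats_for_channel(ch, statistics))
        for (nm in names(bs)) nulls[[ch]][[nm]][b, ] <- bs[[nm]]
      }
    }
  }
  if (record_indices) attr(nulls, "perm_indices") <- perms
  attr(nulls, "B") <- B
  nulls
}

# rebuild the QR pieces for a modified design matrix (same shape)
.redesign <- function(design, Xs) {
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) stop("permuted design is rank deficient")
  Rm <- qr.R(qx)
  design$X <- Xs
  design$Q <- qr.Q(qx)
  design$R <- Rm
  design$XtXinv <- chol2inv(Rm)
  design
}

#' Run the full network-pair enrichment analysis
#'
#' Computes the observed block statistics for every channel (t for SA, t for
#' RRB, joint partial F) and requested statistic (ORA, max-mean on t channels,
#' GSEA), draws permutation nulls (statistics sharing a permutation count
#' share one ensemble; counts differing per statistic get independent
#' streams), and assigns add-one permutation p-values. A block is flagged
#' significant at \code{cfg$alpha_per_test}; a block/channel shows
#' \emph{convergence} when every statistic available for that channel is
#' significant.
#'
#' @inheritParams permute_null
#' @param B Optional single permutation count overriding the per-statistic
#'   counts in \code{cfg} (convenient for simulation studies).
#' @return Data frame with one row per block x channel x statistic:
#'   \code{net_a}, \code{net_b}, \code{k}, \code{channel}, \code{statistic},
#'   \code{observed}, \code{p}, \code{B}, \code{significant},
#'   \code{convergence}. Analysis settings are attached as attributes
#'   (\code{"ea_config"}).
#' @export
run_ea <- function(fc, design, blocks, cfg = ea_config(), B = NULL,
                   channels = c("t_sa", "t_rrb", "f_joint"),
                   statistics = c("ora", "maxmean", "gsea")) {
  stopifnot(inherits(blocks, "fcea_blocks"))
  channels <- match.arg(channels, several.ok = TRUE)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (any(.colVars(fc) <= .Machine$double.eps))
    stop("fc contains zero-variance pairs; remove them before enrichment")
  df <- design$residual_df
  st_obs <- .screen_stats(fc, design)

  B_map <- c(ora = cfg$B_ora, maxmean = cfg$B_maxmean, gsea = cfg$B_gsea)
  if (!is.null(B)) B_map[] <- as.integer(B)
  B_map <- B_map[statistics]

  nulls <- list()
  for (gi in seq_along(unique(B_map))) {
    Bg <- unique(B_map)[gi]
    stats_g <- names(B_map)[B_map == Bg]
    ng <- permute_null(fc, design, blocks, cfg, B = Bg,
                       channels = channels, statistics = stats_g,
                       seed = cfg$seed + gi - 1L)
    for (ch in names(ng))
      for (nm in names(ng[[ch]]))
        nulls[[ch]][[nm]] <- ng[[ch]][[nm]]
  }

  bl <- blocks$blocks
  rows <- list()
  for (ch in channels) {
    s <- st_obs[[ch]]
    stats_ch <- .stats_for_channel(ch, statistics)
    obs <- .block_stats_all(s, .chan_type(ch), blocks, cfg, df, stats_ch)
    pmat <- sapply(stats_ch, function(nm) {
      vapply(seq_len(nrow(bl)), function(bidx) {
        if (is.na(obs[[nm]][bidx])) return(NA_real_)
        perm_pvalue(obs[[nm]][bidx], nulls[[ch]][[nm]][, bidx])
      }, numeric(1))
    })
    pmat <- matrix(pmat, nrow = nrow(bl),
                   dimnames = list(NULL, stats_ch))
    sig <- pmat < cfg$alpha_per_test
    conv <- apply(sig, 1L, function(x) if (anyNA(x)) NA else all(x))
    for (nm in stats_ch) {
      rows[[length(rows) + 1L]] <- data.frame(
        net_a = bl$net_a, net_b = bl$net_b, k = bl$k,
        channel = ch, statistic = nm,
        observed = obs[[nm]], p = pmat[, nm],
        B = unname(B_map[nm]),
        significant = sig[, nm], convergence = conv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ea_config") <- cfg
  out
}

#' Estimate the experiment-wide false-positive rate under the null
#'
#' Estimates \code{P(min over blocks of the permutation p-value <
#' alpha_per_test)} under a global null (no connectivity-behavior coupling)
#' by direct replication: each simulated null cohort receives its own
#' permutation test of every block, and the fraction of cohorts whose
#' smallest block p-value clears the per-test level is reported. The
#' permutation loop stops early for a cohort as soon as every block has
#' accumulated two null exceedances, since its add-one p-value can then no
#' longer resolve \code{alpha_per_test} (the minimum-p distribution is what
#' Westfall-Young resampling targets; here it is sampled exactly). The
#' independent-blocks closed form
#' \code{1 - (1 - alpha_per_test)^n_blocks} is returned alongside; for a
#' continuous block statistic the per-block exceedance probability is
#' exactly \code{2/(B+1)}, so the estimate concentrates at the closed form,
#' while the discrete ORA statistic is conservative at reduced block sizes.
#'
#' @param n_subjects,n_rois Reduced simulation dimensions (defaults 60 and
#'   100, the package's standard desk-scale study conditions).
#' @param B Permutations per cohort (must satisfy
#'   \code{(B + 1) * alpha_per_test >= 2}, else the add-one p-value can never
#'   resolve \code{alpha_per_test}).
#' @param n_datasets Number of null cohorts simulated.
#' @param alpha_per_test Per-block significance level (default 0.0005).
#' @param statistic,channel Which block statistic and screening channel to
#'   calibrate on. The default is max-mean on the SA t channel: it is
#'   continuous, so its permutation p-values are exact where the discrete
#'   ORA lattice at desk-scale block sizes would be conservative.
#' @param cfg A null \code{\link{sim_config}} (its coupling must be absent
#'   or have slope 0).
#' @param ea_cfg An \code{\link{ea_config}}.
#' @param seed Integer seed.
#' @return List: \code{estimate}, \code{analytic} (closed form),
#'   \code{n_blocks}, \code{hit} (per-cohort logical), \code{B},
#'   \code{n_datasets}.
#' @export
calibrate_fwer <- function(n_subjects = 60L, n_rois = 100L, B = 4000L,
                           n_datasets = 500L, alpha_per_test = 5e-4,
                           statistic = "maxmean", channel = "t_sa",
                           cfg = NULL, ea_cfg = ea_config(), seed = 1L) {
  if ((B + 1) * alpha_per_test < 2)
    stop("B too small to resolve alpha_per_test = ", alpha_per_test,
         "; need B >= ", ceiling(2 / alpha_per_test - 1))
  if (is.null(cfg)) cfg <- sim_config(n_subjects = n_subjects)
  if (!is.null(cfg$coupling) && cfg$coupling$slope != 0)
    stop("calibrate_fwer requires a null generator (coupling slope 0)")
  chan_type <- .chan_type(channel)

  parc <- filter_parcellation(gen_parcellation(n_rois, seed = seed))
  blocks <- define_blocks(parc)
  nonempty <- which(blocks$blocks$k > 0L)
  # p < alpha is only attainable while a block's exceedance count is < this
  max_count <- ceiling(alpha_per_test * (B + 1)) - 1L
  stages <- unique(c(min(300L, B), min(1200L, B), B))

  hit <- vapply(seq_len(n_datasets), function(d) {
    coh <- gen_cohort(cfg, seed = seed + d)
    fc <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg,
                           seed = seed + d)
    design <- build_design(coh$subjects, coh$behaviors)
    obs <- .block_stats_all(.screen_stats(fc, design)[[channel]],
                            chan_type, blocks, ea_cfg, design$residual_df,
                            statistic)[[statistic]][nonempty]
    count <- integer(length(nonempty))
    b_done <- 0L
    for (stage in stages) {
      nulls <- permute_null(fc, design, blocks, ea_cfg, B = stage - b_done,
                            channels = channel, statistics = statistic,
                            seed = seed * 100L + d * 10L +
                              match(stage, stages))[[channel]][[statistic]]
      count <- count + colSums(nulls[, nonempty, drop = FALSE] >=
                                 rep(obs, each = nrow(nulls)))
      b_done <- stage
      if (all(count > max_count)) return(FALSE)
    }
    any((count + 1) / (B + 1) < alpha_per_test)
  }, logical(1))

  list(estimate = mean(hit),
       analytic = 1 - (1 - alpha_per_test)^length(nonempty),
       n_blocks = length(nonempty),
       n_blocks_total = nrow(blocks$blocks),
       hit = hit, B = B, n_datasets = as.integer(n_datasets))
}
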