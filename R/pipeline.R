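#' Run the simulate-screen-enrich-report pipeline
#'
#' Composes the package's stages end to end on a synthetic cohort: generate
#' and filter a parcellation, generate the cohort and its connectivity,
#' build the design, screen all ROI pairs, run the network-pair enrichment
#' analysis, and extract hits for the block of interest. Three presets cover
#' the standard study conditions:
#' \describe{
#'   \item{null}{60 subjects, 100 ROIs, no coupling (exchangeable null).}
#'   \item{planted}{60 subjects, 100 ROIs, SAL-Vis coupling to SA calibrated
#'     for decisive recovery (mean within-block |t| about 2; see
#'     \code{\link{calibrate_slope}}).}
#'   \item{study-dims}{97 subjects, 300 ROIs with 3 unassigned and 9
#'     QC-failing (288 retained in 13 networks), same planted coupling.}
#' }
#' All stages are seeded; reruns with identical arguments give identical
#' outputs, including the permutation streams. Attrition counts are logged.
#'
#' @param preset One of \code{"null"}, \code{"planted"},
#'   \code{"study-dims"}.
#' @param seed Integer master seed.
#' @param exclude_sleepers Drop subjects with \code{sleep_flag} before model
#'   building (the sensitivity rerun; pair ordering is unchanged so tables
#'   remain comparable).
#' @param B Permutation count applied to all statistics (kept modest by
#'   default; raise for confirmatory runs).
#' @param cfg Optional \code{\link{sim_config}} overriding the preset's.
#' @param ea_cfg Optional \code{\link{ea_config}}; its seed is tied to
#'   \code{seed}.
#' @param target_mean_abs_t Effect-size target for the planted coupling
#'   calibration (default 2).
#' @return List: \code{parcellation}, \code{subjects}, \code{behaviors},
#'   \code{fc}, \code{design}, \code{screening}, \code{blocks},
#'   \code{enrichment}, \code{hits} (classified, for the target or top
#'   block), \code{target} (net pair character or NULL), \code{summary}
#'   (run metadata: preset, seed, counts, slope).
#' @export
run_pipeline <- function(preset = c("null", "planted", "study-dims"),
                         seed = 1L, exclude_sleepers = FALSE, B = 1999L,
                         cfg = NULL, ea_cfg = NULL,
                         target_mean_abs_t = 2) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)

  dims <- switch(preset,
    "null"       = list(n = 60L, rois = 100L, unassigned = 0L,
                        qc_fail = integer(), planted = FALSE),
    "planted"    = list(n = 60L, rois = 100L, unassigned = 0L,
                        qc_fail = integer(), planted = TRUE),
    "study-dims" = list(n = 97L, rois = 300L, unassigned = 3L,
                        qc_fail = 1:9, planted = TRUE))

  if (is.null(cfg)) cfg <- sim_config(n_subjects = dims$n)
  if (is.null(ea_cfg)) ea_cfg <- ea_config(seed = seed)

  parc_full <- gen_parcellation(dims$rois, dims$unassigned, dims$qc_fail,
                                seed = seed)
  parc <- filter_parcellation(parc_full)
  coh <- gen_cohort(cfg, seed = seed)
  subjects <- coh$subjects
  behaviors <- coh$behaviors

  target <- NULL
  if (dims$planted) {
    target <- c("SAL", "Vis")
    des0 <- build_design(subjects, behaviors)
    slope <- calibrate_slope(des0, cfg, target_mean_abs_t, behavior = "SA")
    cfg$coupling <- list(networks = target, behavior = "SA", slope = slope)
    message("run_pipeline: planted SAL-Vis x SA coupling, slope ",
            signif(slope, 4))
  }
  fc <- gen_connectivity(subjects, behaviors, parc, cfg, seed = seed)

  if (exclude_sleepers) {
    keep <- !subjects$sleep_flag
    message("run_pipeline: sensitivity rerun excluding ", sum(!keep),
            " sleeping subject(s); ", sum(keep), " retained")
    subjects <- subjects[keep, , drop = FALSE]
    behaviors <- behaviors[keep, , drop = FALSE]
    pidx_keep <- attr(fc, "pair_index")
    fc <- fc[keep, , drop = FALSE]
    attr(fc, "pair_index") <- pidx_keep
  }

  design <- build_design(subjects, behaviors)
  message("run_pipeline: design with ", design$n, " subjects, ",
          design$p, " columns, residual df ", design$residual_df)
  screening <- screen_all(fc, design)
  blocks <- define_blocks(parc)
  ea <- run_ea(fc, design, blocks, ea_cfg, B = B)

  # hits for the target block (planted) or the block with the smallest
  # SA-channel p-value
  pidx <- attr(fc, "pair_index")
  if (!is.null(target)) {
    bsel <- which((blocks$blocks$net_a %in% target) &
                    (blocks$blocks$net_b %in% target) &
                    blocks$blocks$net_a != blocks$blocks$net_b)
  } else {
    sa <- ea[ea$channel == "t_sa" & !is.na(ea$p), ]
    top <- sa[which.min(sa$p), c("net_a", "net_b")]
    bsel <- which(blocks$blocks$net_a == top$net_a &
                    blocks$blocks$net_b == top$net_b)
  }
  members <- blocks$idx[[bsel]]
  hits <- identify_hits(screening$t_sa, members, pidx = pidx)
  hits <- classify_hits(hits, parc)

  summary <- list(preset = preset, seed = seed,
                  exclude_sleepers = exclude_sleepers, B = B,
                  n_subjects = design$n, n_rois = nrow(parc),
                  n_rois_input = nrow(parc_full),
                  n_pairs = ncol(fc), n_blocks = nrow(blocks$blocks),
                  residual_df = design$residual_df,
                  slope = if (dims$planted) cfg$coupling$slope else 0,
                  target = target,
                  package_version = as.character(utils::packageVersion("fcea")))

  list(parcellation = parc, subjects = subjects, behaviors = behaviors,
       fc = fc, design = design, screening = screening, blocks = blocks,
       enrichment = ea, hits = hits, target = target, summary = summary)
}
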