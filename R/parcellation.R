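#' Generate a synthetic spherical-ROI parcellation
#'
#' Builds an ROI table modeled on functionally defined whole-brain parcellations
#' (300-ROI scale; cortical, subcortical and cerebellar spheres assigned to 13
#' functional networks). Network sizes follow fixed realistic proportions (large
#' visual/default-mode/somatomotor networks, small salience/parietomedial
#' networks), every network receives at least one ROI, and a configurable
#' number of ROIs is left without a network assignment. ROIs listed in
#' \code{qc_fail_ids} are marked as failing quality control.
#'
#' @param n_rois Total number of ROIs (must be at least 13).
#' @param n_unassigned Number of ROIs left without a network label (the
#'   \code{"unassigned"} sentinel). Unassigned ROIs are chosen among ROIs that
#'   pass QC so that attrition counts are additive.
#' @param qc_fail_ids Integer vector of ROI ids (1..n_rois) flagged as failing
#'   quality control. Must not contain duplicates.
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return Data frame with columns \code{roi_id}, \code{x}, \code{y}, \code{z}
#'   (atlas mm, informational), \code{hemisphere} (\code{"L"}, \code{"R"},
#'   \code{"M"}), \code{anat_class} (\code{"cortical"}, \code{"subcortical"},
#'   \code{"cerebellar"}), \code{network} (one of \code{\link{fcea_networks}()}
#'   or \code{"unassigned"}) and \code{qc_pass} (logical).
#' @seealso \code{\link{filter_parcellation}}
#' @export
#' @examples
#' p <- gen_parcellation(300, n_unassigned = 3, qc_fail_ids = 1:9, seed = 1)
#' table(p$network)
gen_parcellation <- function(n_rois, n_unassigned = 0L, qc_fail_ids = integer(),
                             seed = 1L) {
  nets <- fcea_networks()
  n_rois <- as.integer(n_rois)
  n_unassigned <- as.integer(n_unassigned)
  qc_fail_ids <- as.integer(qc_fail_ids)
  if (n_rois < length(nets))
    stop("n_rois (", n_rois, ") must be at least the number of networks (",
         length(nets), ")")
  if (anyDuplicated(qc_fail_ids))
    stop("qc_fail_ids contains duplicates")
  if (length(qc_fail_ids) && (min(qc_fail_ids) < 1L || max(qc_fail_ids) > n_rois))
    stop("qc_fail_ids must lie in 1..n_rois")
  if (n_unassigned + length(qc_fail_ids) >= n_rois)
    stop("n_unassigned + length(qc_fail_ids) must be smaller than n_rois")

  # network size proportions, roughly matching functionally defined
  # whole-brain ROI sets
  w <- c(Vis = 0.135, DMN = 0.21, SMD = 0.13, SML = 0.03, AUD = 0.035,
         DAN = 0.055, VAN = 0.08, PMN = 0.02, FP = 0.08, CO = 0.10,
         MTL = 0.03, REWARD = 0.035, SAL = 0.06)
  w <- w[nets]

  n_assigned <- n_rois - n_unassigned
  counts <- .largest_remainder(w, n_assigned, min_each = 1L)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  labels <- sample(rep(nets, times = counts))
  qc_pass <- !(seq_len(n_rois) %in% qc_fail_ids)
  # unassigned ROIs drawn among QC-passing ROIs so filter counts are additive
  pool <- which(qc_pass)
  una <- if (n_unassigned > 0L) sort(sample(pool, n_unassigned)) else integer()
  network <- character(n_rois)
  network[setdiff(seq_len(n_rois), una)] <- labels
  network[una] <- .unassigned

  hemisphere <- sample(c("L", "R", "M"), n_rois, replace = TRUE,
                       prob = c(0.475, 0.475, 0.05))
  anat_class <- sample(c("cortical", "subcortical", "cerebellar"), n_rois,
                       replace = TRUE, prob = c(0.80, 0.12, 0.08))
  x <- round(stats::runif(n_rois, 5, 70), 1)
  x[hemisphere == "L"] <- -x[hemisphere == "L"]
  x[hemisphere == "M"] <- round(stats::runif(sum(hemisphere == "M"), -4, 4), 1)
  y <- round(stats::runif(n_rois, -100, 70), 1)
  z <- round(stats::runif(n_rois, -45, 75), 1)

  data.frame(roi_id = seq_len(n_rois), x = x, y = y, z = z,
             hemisphere = hemisphere, anat_class = anat_class,
             network = network, qc_pass = qc_pass,
             stringsAsFactors = FALSE)
}

#' Filter a parcellation to QC-passing, network-assigned ROIs
#'
#' Retains ROIs that pass quality control and carry a network assignment;
#' this is the ROI set entering connectivity computation and screening.
#' Emits a message with the attrition count and a warning naming any network
#' that loses all of its ROIs.
#'
#' @param parcellation Parcellation data frame from
#'   \code{\link{gen_parcellation}} (or read from file).
#' @return The filtered parcellation (same columns, subset of rows).
#' @export
#' @examples
#' p <- gen_parcellation(300, 3, 1:9, seed = 1)
#' nrow(filter_parcellation(p))  # 288
filter_parcellation <- function(parcellation) {
  stopifnot(is.data.frame(parcellation),
            all(c("network", "qc_pass") %in% names(parcellation)))
  keep <- parcellation$qc_pass & parcellation$network != .unassigned
  out <- parcellation[keep, , drop = FALSE]
  rownames(out) <- NULL
  nets_in <- setdiff(unique(parcellation$network), .unassigned)
  emptied <- setdiff(nets_in, unique(out$network))
  for (nw in emptied)
    warning("network ", nw, " has no ROIs after filtering", call. = FALSE)
  message("filter_parcellation: retained ", nrow(out), " of ",
          nrow(parcellation), " ROIs in ",
          length(unique(out$network)), " networks")
  out
}

# deterministic proportional apportionment with a per-cell minimum:
# start every cell at the minimum, then hand out the remaining items one by
# one to the cell furthest below its proportional target (ties by order)
.largest_remainder <- function(w, total, min_each = 1L) {
  k <- length(w)
  if (total < k * min_each)
    stop("cannot allocate ", total, " items with minimum ", min_each,
         " over ", k, " cells")
  target <- w / sum(w) * total
  alloc <- rep(min_each, k)
  for (i in seq_len(total - k * min_each)) {
    j <- which.max(target - alloc)
    alloc[j] <- alloc[j] + 1L
  }
  as.integer(alloc)
}

# preserve the caller's RNG state across internally seeded generation
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
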