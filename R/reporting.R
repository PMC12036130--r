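#' Identify screening hits within a block
#'
#' Hits are the ROI pairs whose screening t statistic falls in the brain-wide
#' extreme tails (top \code{tail_fraction} of positive and of negative
#' statistics; default 2.5% each). Thresholds are the brain-wide
#' \code{1 - tail_fraction} and \code{tail_fraction} quantiles of all pair
#' statistics; the queried block's members strictly beyond either threshold
#' are returned, signed. Ties at a threshold are excluded (strict
#' inequality).
#'
#' @param tstats All-pair screening t statistics in canonical pair order.
#' @param members Pair indices of the queried block (default all pairs).
#' @param tail_fraction Tail mass per side, in (0, 0.5).
#' @param pidx Optional \code{\link{pair_index}} table for ROI annotation.
#' @return Data frame of class \code{"fcea_hits"}: \code{pair}, \code{t},
#'   \code{sign} (\code{"positive"}/\code{"negative"}), plus \code{roi_i},
#'   \code{roi_j} when \code{pidx} is given. Thresholds are attached as
#'   attribute \code{"thresholds"}.
#' @export
identify_hits <- function(tstats, members = seq_along(tstats),
                          tail_fraction = 0.025, pidx = NULL) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must lie in (0, 0.5)")
  if (length(members) == 0L) stop("empty block")
  hi <- stats::quantile(tstats, 1 - tail_fraction, names = FALSE)
  lo <- stats::quantile(tstats, tail_fraction, names = FALSE)
  tm <- tstats[members]
  is_hit <- tm > hi | tm < lo
  out <- data.frame(pair = members[is_hit], t = tm[is_hit],
                    sign = ifelse(tm[is_hit] > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(pidx)) {
    m <- match(out$pair, pidx$pair)
    out$roi_i <- pidx$roi_i[m]
    out$roi_j <- pidx$roi_j[m]
  }
  attr(out, "thresholds") <- c(lower = lo, upper = hi)
  class(out) <- c("fcea_hits", "data.frame")
  out
}

#' Classify hits by laterality and anatomical class
#'
#' Annotates each hit pair with laterality (L-R pairs are contralateral, L-L
#' left, R-R right; a pair involving a midline ROI is reported in a separate
#' \code{"midline-involved"} class) and anatomy (\code{"cortico-cortical"}
#' when both ROIs are cortical, otherwise \code{"other"}), and attaches the
#' class proportions.
#'
#' @param hits A \code{\link{identify_hits}} table with \code{roi_i},
#'   \code{roi_j}.
#' @param parcellation Parcellation providing \code{hemisphere} and
#'   \code{anat_class} per ROI.
#' @return The hits table with \code{laterality} and \code{anat} columns;
#'   attribute \code{"summary"} holds proportion tables.
#' @export
classify_hits <- function(hits, parcellation) {
  stopifnot(all(c("roi_i", "roi_j") %in% names(hits)))
  hemi <- parcellation$hemisphere[match(hits$roi_i, parcellation$roi_id)]
  hemj <- parcellation$hemisphere[match(hits$roi_j, parcellation$roi_id)]
  ok <- c("L", "R", "M")
  if (anyNA(hemi) || anyNA(hemj) || !all(c(hemi, hemj) %in% ok))
    stop("unknown hemisphere code among hit ROIs")
  lat <- ifelse(hemi == "M" | hemj == "M", "midline-involved",
         ifelse(hemi != hemj, "contralateral",
         ifelse(hemi == "L", "left", "right")))
  ai <- parcellation$anat_class[match(hits$roi_i, parcellation$roi_id)]
  aj <- parcellation$anat_class[match(hits$roi_j, parcellation$roi_id)]
  anat <- ifelse(ai == "cortical" & aj == "cortical",
                 "cortico-cortical", "other")
  hits$laterality <- lat
  hits$anat <- anat
  summ <- list(
    n = nrow(hits),
    laterality = if (nrow(hits)) prop.table(table(lat)) else table(lat),
    anat = if (nrow(hits)) prop.table(table(anat)) else table(anat),
    positive_fraction = if (nrow(hits)) mean(hits$sign == "positive")
                        else NA_real_)
  attr(hits, "summary") <- summ
  hits
}

#' Stratified connectivity summary for a block
#'
#' Pools a block's connectivity values within behavioral strata (score at or
#' above the cutoff versus below) and summarizes each stratum's location,
#' with the between-stratum shift.
#'
#' @param fc Subjects x pairs connectivity matrix.
#' @param behaviors Behavior table aligned with \code{fc} rows.
#' @param members Pair indices of the block.
#' @param behavior Behavior column used for stratification (default "SA").
#' @param cutoff Stratum boundary; the upper stratum is \code{score >= cutoff}
#'   (default 5).
#' @return List: \code{strata} (data frame with per-stratum n_subjects,
#'   n_values, mean, median, sd) and \code{shift} (upper minus lower stratum
#'   mean).
#' @export
stratified_fc_summary <- function(fc, behaviors, members, behavior = "SA",
                                  cutoff = 5) {
  stopifnot(is.matrix(fc), nrow(fc) == nrow(behaviors))
  score <- as.numeric(behaviors[[behavior]])
  upper <- score >= cutoff
  if (!any(upper)) stop("empty stratum: no subject with ", behavior,
                        " >= ", cutoff)
  if (all(upper)) stop("empty stratum: no subject with ", behavior,
                       " < ", cutoff)
  vals <- function(rows) as.numeric(fc[rows, members, drop = FALSE])
  lo <- vals(!upper); hi <- vals(upper)
  strata <- data.frame(
    stratum = c(paste0(behavior, "<", cutoff), paste0(behavior, ">=", cutoff)),
    n_subjects = c(sum(!upper), sum(upper)),
    n_values = c(length(lo), length(hi)),
    mean = c(mean(lo), mean(hi)),
    median = c(stats::median(lo), stats::median(hi)),
    sd = c(stats::sd(lo), stats::sd(hi)),
    stringsAsFactors = FALSE)
  list(strata = strata, shift = mean(hi) - mean(lo))
}

#' Export a figure-ready ROI x ROI matrix with network ordering
#'
#' Reorders a symmetric ROI matrix (or a pair-statistic vector, which is
#' first symmetrized via \code{\link{pairs_to_matrix}}) network-major in the
#' canonical network order, with subcortical and cerebellar ROIs first within
#' each network followed by cortical ROIs. Optionally writes the matrix and a
#' sidecar of network block boundaries as tab-separated text.
#'
#' @param values ROI x ROI matrix, or a pair vector of length R(R-1)/2.
#' @param parcellation The filtered parcellation the values refer to.
#' @param ordering \code{"network"} (default) or \code{"input"}.
#' @param file Optional path; writes \code{file} (matrix with ROI-id row and
#'   column labels) and \code{paste0(file, ".blocks.tsv")} (network, start,
#'   end row indices).
#' @return List (invisibly when writing): \code{matrix} (reordered),
#'   \code{order} (row permutation applied), \code{boundaries} (data frame
#'   network/start/end).
#' @export
export_matrix <- function(values, parcellation,
                          ordering = c("network", "input"), file = NULL) {
  ordering <- match.arg(ordering)
  R <- nrow(parcellation)
  m <- if (is.matrix(values)) values else pairs_to_matrix(values, parcellation)
  stopifnot(nrow(m) == R, ncol(m) == R)
  if (ordering == "network") {
    nets <- .network_order(unique(parcellation$network))
    subfirst <- parcellation$anat_class != "cortical"
    ord <- order(match(parcellation$network, nets), !subfirst,
                 parcellation$roi_id)
  } else {
    ord <- seq_len(R)
  }
  pm <- m[ord, ord, drop = FALSE]
  dimnames(pm) <- list(parcellation$roi_id[ord], parcellation$roi_id[ord])
  netv <- parcellation$network[ord]
  rle_n <- rle(netv)
  ends <- cumsum(rle_n$lengths)
  boundaries <- data.frame(network = rle_n$values,
                           start = c(1L, utils::head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  out <- list(matrix = pm, order = ord, boundaries = boundaries)
  if (!is.null(file)) {
    utils::write.table(pm, file, sep = "\t", quote = FALSE,
                       col.names = NA)
    utils::write.table(boundaries, paste0(file, ".blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
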