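# Tab-separated text interfaces: one row per subject/ROI/pair, header line,
# missing values as empty fields.

#' Write a table as tab-separated text
#'
#' @param x Data frame.
#' @param file Path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

#' Read a tab-separated table written by \code{\link{write_tsv}}
#'
#' @param file Path.
#' @return Data frame; empty fields become \code{NA}.
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write a subjects x pairs connectivity table
#'
#' First column \code{subject_id}, then one column per ROI pair named
#' \code{"roi_i:roi_j"} in canonical pair order.
#'
#' @param fc Subjects x pairs matrix.
#' @param file Path.
#' @export
write_fc_pairs <- function(fc, file) {
  df <- data.frame(subject_id = rownames(fc), fc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, file)
}

#' Read a subjects x pairs connectivity table
#'
#' @param file Path written by \code{\link{write_fc_pairs}}.
#' @return Subjects x pairs matrix with subject ids as row names.
#' @export
read_fc_pairs <- function(file) {
  df <- utils::read.delim(file, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a per-subject square connectivity matrix
#'
#' @param z ROI x ROI matrix (e.g. from \code{\link{compute_fc}}).
#' @param file Path.
#' @export
write_fc_matrix <- function(z, file) {
  utils::write.table(z, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

#' Serialize screening results with network annotation
#'
#' Writes one row per pair: \code{roi_i}, \code{roi_j}, \code{network_i},
#' \code{network_j}, \code{t_sa}, \code{t_rrb}, \code{f_joint},
#' \code{df_den}.
#'
#' @param screening \code{\link{screen_all}} result.
#' @param pidx \code{\link{pair_index}} table (defaults to the one attached
#'   to the screening result).
#' @param file Path.
#' @export
write_screening <- function(screening, file,
                            pidx = attr(screening, "pair_index")) {
  if (is.null(pidx)) stop("pair_index required to annotate screening output")
  m <- match(screening$pair, pidx$pair)
  out <- data.frame(roi_i = pidx$roi_i[m], roi_j = pidx$roi_j[m],
                    network_i = pidx$net_i[m], network_j = pidx$net_j[m],
                    t_sa = screening$t_sa, t_rrb = screening$t_rrb,
                    f_joint = screening$f_joint, df_den = screening$df_den,
                    stringsAsFactors = FALSE)
  write_tsv(out, file)
}

#' Serialize enrichment results
#'
#' @param ea \code{\link{run_ea}} result.
#' @param file Path.
#' @export
write_enrichment <- function(ea, file) {
  write_tsv(ea, file)
}
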