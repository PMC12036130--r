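#' Censor high-motion frames by framewise displacement
#'
#' Marks frames whose framewise displacement (FD) exceeds the threshold as
#' censored; only frames with \code{fd <= threshold} are retained. No
#' neighbor augmentation is applied.
#'
#' @param ts An \code{"fcea_ts"} object (see \code{\link{gen_timeseries}}).
#' @param threshold FD threshold in mm (default 0.2).
#' @return List of class \code{"fcea_mask"}: \code{retained} (logical per
#'   frame), \code{fd_threshold_mm}, \code{tr} (seconds) and
#'   \code{usable_minutes} (retained frames x tr / 60).
#' @export
#' @examples
#' ts <- list(fd = c(0.10, 0.25, 0.15), tr = 2)
#' censor_frames(structure(ts, class = "fcea_ts"))$retained
censor_frames <- function(ts, threshold = 0.2) {
  if (threshold < 0) stop("FD threshold must be non-negative")
  fd <- ts$fd
  if (is.null(fd) || anyNA(fd)) stop("fd must be defined for every frame")
  retained <- fd <= threshold
  structure(list(retained = retained, fd_threshold_mm = threshold,
                 tr = ts$tr,
                 usable_minutes = sum(retained) * ts$tr / 60),
            class = "fcea_mask")
}

#' Subject-level usable-data quality control
#'
#' A subject passes when the censored time series retains at least
#' \code{min_minutes} of data; the comparison is inclusive.
#'
#' @param mask A frame mask from \code{\link{censor_frames}}.
#' @param min_minutes Minimum usable minutes (default 7).
#' @return Logical scalar.
#' @export
subject_qc <- function(mask, min_minutes = 7) {
  stopifnot(inherits(mask, "fcea_mask"))
  mask$usable_minutes >= min_minutes
}

#' Nuisance regression of ROI time series
#'
#' Regresses each ROI's series on an intercept, a linear trend, the nuisance
#' channels and their backward-difference derivatives (first frame 0). The
#' fit uses only retained frames (so censored high-motion frames cannot
#' leverage the fit), but residuals are formed for all frames so that
#' temporal filtering can run on a gap-free series. Demeaning and detrending
#' are realized by the constant and trend columns.
#'
#' @param ts An \code{"fcea_ts"} object.
#' @param mask Optional frame mask (\code{\link{censor_frames}}); default
#'   retains all frames.
#' @return The input object with \code{series} replaced by residuals.
#' @export
nuisance_regress <- function(ts, mask = NULL) {
  x <- ts$series
  n <- nrow(x)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask$retained
  stopifnot(length(keep) == n)

  trend <- seq_len(n) - (n + 1) / 2
  reg <- cbind(intercept = 1, trend = trend / max(abs(trend)))
  if (!is.null(ts$nuisance) && NCOL(ts$nuisance) > 0) {
    nu <- as.matrix(ts$nuisance)
    dn <- rbind(0, diff(nu))
    colnames(dn) <- paste0("d_", colnames(nu))
    reg <- cbind(reg, nu, dn)
  }

  qx <- qr(reg[keep, , drop = FALSE])
  if (qx$rank < ncol(reg)) {
    bad <- colnames(reg)[qx$pivot[(qx$rank + 1L):ncol(reg)]]
    stop("nuisance regressor matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, x[keep, , drop = FALSE])
  ts$series <- x - reg %*% beta
  ts
}

#' Zero-phase band-pass filtering of ROI time series
#'
#' Applies a zero-phase Butterworth band-pass (forward-backward filtering) to
#' each ROI series. When a frame mask is supplied, censored frames are first
#' replaced by linear interpolation over the gaps so that the filter does not
#' see discontinuities; the mask itself is unchanged and should be re-applied
#' downstream (e.g. by \code{\link{compute_fc}}).
#'
#' @param ts An \code{"fcea_ts"} object.
#' @param f_lo,f_hi Pass-band edges in Hz (defaults 0.009 and 0.08).
#' @param mask Optional frame mask used for gap interpolation.
#' @param order Butterworth order per pass (default 2; forward-backward
#'   filtering doubles the effective order).
#' @return The input object with \code{series} filtered.
#' @export
bandpass <- function(ts, f_lo = 0.009, f_hi = 0.08, mask = NULL, order = 2L) {
  nyq <- 1 / (2 * ts$tr)
  if (f_hi >= nyq)
    stop("upper band edge (", f_hi, " Hz) must be below Nyquist (", nyq, " Hz)")
  if (f_lo <= 0 || f_lo >= f_hi) stop("need 0 < f_lo < f_hi")
  x <- ts$series
  n <- nrow(x)
  if (!is.null(mask) && !all(mask$retained)) {
    keep <- which(mask$retained)
    if (length(keep) < 2L) stop("too few retained frames to interpolate")
    for (j in seq_len(ncol(x)))
      x[, j] <- stats::approx(keep, x[keep, j], xout = seq_len(n),
                              rule = 2)$y
  }
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  for (j in seq_len(ncol(x)))
    x[, j] <- signal::filtfilt(bf, x[, j])
  ts$series <- x
  ts
}

#' Fisher-z functional connectivity from a time series
#'
#' Pearson correlations over retained frames, Fisher-z transformed
#' (\code{atanh}). The diagonal is undefined and set to \code{NA}; an ROI
#' with (numerically) zero variance on the retained frames, or an off-diagonal
#' correlation of magnitude 1 (duplicated series), is an error.
#'
#' @param ts An \code{"fcea_ts"} object.
#' @param mask Optional frame mask; default retains all frames.
#' @return ROI x ROI symmetric matrix of Fisher-z correlations with ROI ids
#'   as dimnames and attribute \code{"subject_id"}.
#' @export
compute_fc <- function(ts, mask = NULL) {
  x <- ts$series
  keep <- if (is.null(mask)) rep(TRUE, nrow(x)) else mask$retained
  if (sum(keep) < 2L) stop("need at least 2 retained frames")
  xr <- x[keep, , drop = FALSE]
  v <- apply(xr, 2L, stats::var)
  if (any(v <= .Machine$double.eps)) {
    bad <- colnames(x)[v <= .Machine$double.eps]
    stop("zero-variance ROI(s) on retained frames: ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(xr)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    w <- which(upper.tri(r), arr.ind = TRUE)
    bad <- w[off >= 1 - 1e-12, , drop = FALSE]
    stop("perfectly correlated ROI pair(s) (infinite Fisher z): ",
         paste(apply(bad, 1L, function(ij)
           paste0(colnames(r)[ij[1]], ":", colnames(r)[ij[2]])),
           collapse = ", "))
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  attr(z, "subject_id") <- ts$subject_id
  z
}

#' Group-mean Fisher-z connectivity matrix
#'
#' Element-wise mean of per-subject Fisher-z matrices over a common
#' parcellation.
#'
#' @param matrices List of ROI x ROI matrices from \code{\link{compute_fc}}
#'   (or built with \code{\link{pairs_to_matrix}}).
#' @return ROI x ROI mean matrix.
#' @export
group_mean_fc <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  dn <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), dim(matrices[[1]])) ||
        !identical(dimnames(m), dn))
      stop("connectivity matrices have mismatched ROI sets")
  }
  out <- Reduce(`+`, matrices) / length(matrices)
  dimnames(out) <- dn
  out
}

#' Stack per-subject connectivity matrices into a subjects x pairs table
#'
#' @param matrices Named list of ROI x ROI Fisher-z matrices (names or
#'   \code{"subject_id"} attributes identify subjects).
#' @param parcellation The filtered parcellation defining pair order.
#' @return Subjects x pairs matrix with \code{\link{pair_index}} attribute,
#'   as produced by \code{\link{gen_connectivity}}.
#' @export
stack_fc <- function(matrices, parcellation) {
  pidx <- pair_index(parcellation)
  rows <- t(vapply(matrices, matrix_to_pairs, numeric(nrow(pidx))))
  ids <- vapply(seq_along(matrices), function(i) {
    sid <- attr(matrices[[i]], "subject_id")
    if (!is.null(sid)) sid
    else if (!is.null(names(matrices))) names(matrices)[i]
    else as.character(i)
  }, character(1))
  dimnames(rows) <- list(ids, pidx$name)
  attr(rows, "pair_index") <- pidx
  rows
}
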