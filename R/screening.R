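#' Build the screening design matrix
#'
#' Assembles the fixed-effects design for per-pair regression of connectivity
#' on behaviors and covariates: intercept, site dummies (reference-coded,
#' first site alphabetically as reference), a male dummy, mean-centered age,
#' the four adjustment behaviors (GAD, CONP, LIMB, DAS), optionally a
#' medication dummy, and finally the two tested behaviors SA and RRB. The
#' tested columns are placed last so that the joint partial F test can reuse
#' the sequential decomposition. The residual degrees of freedom are
#' \code{n - ncol(X)}; with 4 sites and no medication term this is
#' \code{n - 12} (85 for 97 subjects, 77 for 89).
#'
#' @param subjects,behaviors Tables as from \code{\link{gen_cohort}}; rows
#'   are matched on \code{subject_id} and behaviors must be complete.
#' @param medication Include a medication dummy (off by default).
#' @param center_age Mean-center age before fitting (does not change t or F).
#' @return List of class \code{"fcea_design"}: \code{X} (n x p matrix),
#'   \code{idx_test} (columns of SA and RRB), \code{residual_df},
#'   \code{XtXinv}, and the QR pieces used by the screening engine.
#' @export
build_design <- function(subjects, behaviors, medication = FALSE,
                         center_age = TRUE) {
  stopifnot(is.data.frame(subjects), is.data.frame(behaviors))
  ord <- match(subjects$subject_id, behaviors$subject_id)
  if (anyNA(ord)) stop("behaviors missing for subject(s): ",
                       paste(subjects$subject_id[is.na(ord)], collapse = ", "))
  beh <- behaviors[ord, , drop = FALSE]
  need <- c("SA", "RRB", "GAD", "CONP", "LIMB", "DAS")
  if (anyNA(beh[need]))
    stop("missing behavior values; subjects with incomplete behavior must be ",
         "removed before model building")
  n <- nrow(subjects)

  const <- need[vapply(beh[need], function(x) stats::var(as.numeric(x)) == 0,
                       logical(1))]
  if (length(const))
    stop("behavior column(s) constant across subjects (inestimable ",
         "coefficient): ", paste(const, collapse = ", "))

  sites <- sort(unique(subjects$site))
  X <- matrix(1, n, 1, dimnames = list(subjects$subject_id, "(Intercept)"))
  if (length(sites) >= 2L) {
    for (s in sites[-1])
      X <- cbind(X, as.numeric(subjects$site == s))
    colnames(X)[(ncol(X) - length(sites) + 2L):ncol(X)] <-
      paste0("site", sites[-1])
  } else {
    warning("only one site represented; site term dropped", call. = FALSE)
  }
  X <- cbind(X, sexM = as.numeric(subjects$sex == "M"))
  age <- subjects$age
  if (center_age) age <- age - mean(age)
  X <- cbind(X, age = age)
  for (v in c("GAD", "CONP", "LIMB", "DAS"))
    X <- cbind(X, as.numeric(beh[[v]]))
  colnames(X)[(ncol(X) - 3L):ncol(X)] <- c("GAD", "CONP", "LIMB", "DAS")
  if (medication)
    X <- cbind(X, medication = as.numeric(subjects$medication_flag))
  X <- cbind(X, SA = as.numeric(beh$SA), RRB = as.numeric(beh$RRB))

  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- n - p
  if (df <= 0) stop("no residual degrees of freedom (n = ", n,
                    ", p = ", p, ")")
  if (df < 10) warning("small residual degrees of freedom (", df, ")",
                       call. = FALSE)

  Q <- qr.Q(qx)
  Rm <- qr.R(qx)
  # qr pivots only on rank deficiency, which is excluded above; assert anyway
  stopifnot(identical(qx$pivot, seq_len(p)))
  structure(list(X = X, idx_test = c(p - 1L, p - 0L),
                 residual_df = df, n = n, p = p,
                 Q = Q, R = Rm, XtXinv = chol2inv(Rm),
                 columns = colnames(X)),
            class = "fcea_design")
}

# core vectorized screening: Y is n x P; returns t for the two tested
# columns, the joint partial F, and the residual SSE per pair.
# Exploits the sequential QR: the tested columns are last, so the reduced
# model's fit is the full fit minus the last two orthogonal components.
.screen_stats <- function(Y, design) {
  p <- design$p
  df <- design$residual_df
  QtY <- crossprod(design$Q, Y)
  sse_full <- colSums(Y * Y) - colSums(QtY^2)
  sse_full[sse_full < 0] <- 0
  extra <- QtY[p - 1L, ]^2 + QtY[p, ]^2
  sigma2 <- sse_full / df
  # back-substitute only the last two coefficient rows (tested columns last)
  Rm <- design$R
  b_rrb <- QtY[p, ] / Rm[p, p]
  b_sa <- (QtY[p - 1L, ] - Rm[p - 1L, p] * b_rrb) / Rm[p - 1L, p - 1L]
  i_sa <- design$idx_test[1]; i_rrb <- design$idx_test[2]
  se_sa <- sqrt(sigma2 * design$XtXinv[i_sa, i_sa])
  se_rrb <- sqrt(sigma2 * design$XtXinv[i_rrb, i_rrb])
  list(t_sa = b_sa / se_sa,
       t_rrb = b_rrb / se_rrb,
       f_joint = (extra / 2) / sigma2,
       sse = sse_full)
}

#' Screen one ROI pair
#'
#' Ordinary-least-squares fit of one connectivity vector on the design;
#' returns the two-sided t statistics for SA and RRB and the partial F for
#' dropping both (numerator df 2, denominator df \code{n - rank(X)}).
#'
#' @param y Per-subject connectivity for one ROI pair (length n).
#' @param design A \code{\link{build_design}} object.
#' @return List with \code{t_sa}, \code{t_rrb}, \code{f_joint}, \code{df}
#'   (c(2, residual_df)).
#' @export
screen_pair <- function(y, design) {
  stopifnot(inherits(design, "fcea_design"))
  y <- as.numeric(y)
  if (length(y) != design$n) stop("length(y) must equal the design's n")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains non-finite values")
  st <- .screen_stats(matrix(y, ncol = 1), design)
  if (st$sse <= .Machine$double.eps * sum(y^2))
    stop("zero residual variance: y is (numerically) in the design's span")
  list(t_sa = unname(st$t_sa), t_rrb = unname(st$t_rrb),
       f_joint = unname(st$f_joint), df = c(2L, design$residual_df))
}

#' Screen all ROI pairs
#'
#' Vectorized per-pair regression over a subjects x pairs connectivity table,
#' reusing one QR decomposition of the shared design. Pairs with zero
#' connectivity variance across subjects are dropped with a logged list.
#'
#' @param fc Subjects x pairs matrix (\code{\link{gen_connectivity}} or
#'   \code{\link{stack_fc}}), rows aligned with the design.
#' @param design A \code{\link{build_design}} object.
#' @return Data frame with one row per retained pair: \code{pair} (canonical
#'   index), \code{name}, \code{t_sa}, \code{t_rrb}, \code{f_joint},
#'   \code{df_den}; the dropped pair indices are in attribute
#'   \code{"dropped"}, the design's pair metadata (when present on \code{fc})
#'   in attribute \code{"pair_index"}.
#' @export
screen_all <- function(fc, design) {
  stopifnot(inherits(design, "fcea_design"), is.matrix(fc))
  if (nrow(fc) != design$n)
    stop("fc has ", nrow(fc), " rows but the design expects ", design$n)
  if (anyNA(fc) || any(!is.finite(fc))) {
    bad <- which(!is.finite(fc), arr.ind = TRUE)
    stop("non-finite connectivity for subject/pair: ",
         paste(utils::head(paste0(rownames(fc)[bad[, 1]], "@",
                                  colnames(fc)[bad[, 2]]), 5L),
               collapse = ", "))
  }
  v <- unname(.colVars(fc))
  dropped <- which(v <= .Machine$double.eps)
  keep <- setdiff(seq_len(ncol(fc)), dropped)
  if (length(dropped))
    message("screen_all: dropped ", length(dropped),
            " zero-variance pair(s): ",
            paste(utils::head(colnames(fc)[dropped], 10L), collapse = ", "))
  st <- .screen_stats(fc[, keep, drop = FALSE], design)
  out <- data.frame(pair = keep,
                    name = colnames(fc)[keep],
                    t_sa = unname(st$t_sa), t_rrb = unname(st$t_rrb),
                    f_joint = unname(st$f_joint),
                    df_den = design$residual_df,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "pair_index") <- attr(fc, "pair_index")
  out
}

.colVars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
}

#' Motion-confound check: framewise displacement versus connectivity
#'
#' Correlates each pair's connectivity with the subjects' mean framewise
#' displacement within a block of interest, to check that a block-level
#' finding is not motion-driven.
#'
#' @param fc Subjects x pairs connectivity matrix.
#' @param mean_fd Per-subject mean FD (mm), aligned with \code{fc} rows.
#' @param members Pair indices (columns of \code{fc}) forming the block;
#'   default all pairs.
#' @return List with \code{per_pair} (data frame: \code{pair}, \code{cor})
#'   and \code{summary} (mean, median, sd, range of the correlations, and a
#'   one-sample t-test p-value for mean zero).
#' @export
fd_confound_check <- function(fc, mean_fd, members = seq_len(ncol(fc))) {
  stopifnot(is.matrix(fc), length(mean_fd) == nrow(fc))
  if (nrow(fc) < 3L)
    stop("need at least 3 subjects for a correlation check")
  if (stats::sd(mean_fd) == 0) stop("mean FD has zero variance")
  members <- as.integer(members)
  cors <- as.numeric(stats::cor(mean_fd, fc[, members, drop = FALSE]))
  tt <- stats::t.test(cors)
  list(per_pair = data.frame(pair = members, cor = cors),
       summary = list(mean = mean(cors), median = stats::median(cors),
                      sd = stats::sd(cors), range = range(cors),
                      p_mean_zero = tt$p.value))
}
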