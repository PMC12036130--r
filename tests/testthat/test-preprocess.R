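test_that("frame censoring follows the FD threshold rule", {
  ts <- toy_ts(matrix(rnorm(30), 3), fd = c(0.10, 0.25, 0.15))
  m <- censor_frames(ts, 0.2)
  expect_equal(m$retained, c(TRUE, FALSE, TRUE))
  expect_equal(m$usable_minutes, 2 * 2 / 60)

  ts0 <- toy_ts(matrix(rnorm(30), 3), fd = rep(0, 3))
  expect_true(all(censor_frames(ts0, 0.2)$retained))
  expect_equal(censor_frames(ts, 0)$retained, rep(FALSE, 3))
  expect_error(censor_frames(ts, -0.1), "non-negative")
})

test_that("usable-minutes QC is inclusive at the 7-minute boundary", {
  frames <- 336  # 11.2 min at tr = 2
  mk <- function(n_censored) {
    fd <- rep(0.1, frames)
    if (n_censored > 0) fd[seq_len(n_censored)] <- 0.5
    censor_frames(toy_ts(matrix(0, frames, 1), fd = fd))
  }
  # ~40% censored: ~6.72 usable minutes (11.2 * 0.6) -> fail
  m40 <- mk(round(0.4 * frames))
  expect_equal(m40$usable_minutes, 6.72, tolerance = 0.01)
  expect_false(subject_qc(m40))
  # nothing censored: 11.2 min -> pass
  expect_true(subject_qc(mk(0)))
  # exactly 7.0 minutes (210 frames) -> pass (inclusive)
  m7 <- mk(frames - 210)
  expect_equal(m7$usable_minutes, 7)
  expect_true(subject_qc(m7))
})

test_that("nuisance regression removes injected artifacts", {
  set.seed(1)
  n <- 200
  nuis <- matrix(rnorm(n * 9), n, 9,
                 dimnames = list(NULL, c("csf", "wm", "global", paste0("m", 1:6))))
  # ROI equal to the global signal regresses to ~0
  x <- cbind(nuis[, "global"], rnorm(n))
  ts <- toy_ts(x, nuisance = nuis)
  out <- nuisance_regress(ts)
  expect_lt(max(abs(out$series[, 1])), 1e-10)

  # injected artifact = 2x CSF: residual correlation with CSF vanishes
  x2 <- matrix(rnorm(n * 3), n, 3)
  x2[, 2] <- x2[, 2] + 2 * nuis[, "csf"]
  out2 <- nuisance_regress(toy_ts(x2, nuisance = nuis))
  expect_lt(abs(cor(out2$series[, 2], nuis[, "csf"])), 1e-10)

  # no nuisance channels: output is the detrended input
  tr_in <- 1:n + rnorm(n)
  out3 <- nuisance_regress(toy_ts(cbind(tr_in)))
  fit <- lm(tr_in ~ seq_len(n))
  expect_equal(unname(out3$series[, 1]), unname(residuals(fit)),
               tolerance = 1e-8)

  # collinear channels are rejected with names
  bad <- nuis
  bad[, "wm"] <- bad[, "csf"]
  expect_error(nuisance_regress(toy_ts(x2, nuisance = bad)),
               "rank deficient")
})

test_that("regression fitted on retained frames ignores censored spikes", {
  set.seed(2)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2)
  spiked <- x
  spiked[75, ] <- spiked[75, ] + 50  # huge artifact at one censored frame
  fd <- rep(0.05, n); fd[75] <- 2.0
  mask <- censor_frames(toy_ts(spiked, fd = fd))
  out_sp <- nuisance_regress(toy_ts(spiked, fd = fd), mask)
  out_cl <- nuisance_regress(toy_ts(x, fd = fd), mask)
  keep <- mask$retained
  expect_equal(out_sp$series[keep, ], out_cl$series[keep, ],
               tolerance = 1e-10)
})

test_that("band-pass attenuates stop band and preserves pass band", {
  tr <- 2
  n <- 1024
  tt <- seq_len(n) * tr
  pow <- function(x) mean(x^2)
  # 0.2 Hz sinusoid: deep in the stop band
  hi <- sin(2 * pi * 0.2 * tt)
  out_hi <- bandpass(toy_ts(cbind(hi), tr = tr))$series[, 1]
  expect_lt(pow(out_hi[100:900]) / pow(hi), 0.01)
  # 0.03 Hz sinusoid: pass band, within 1 dB
  lo <- sin(2 * pi * 0.03 * tt)
  out_lo <- bandpass(toy_ts(cbind(lo), tr = tr))$series[, 1]
  ratio <- pow(out_lo[100:900]) / pow(lo[100:900])
  expect_gt(ratio, 10^(-1 / 10))
  expect_lt(ratio, 10^(1 / 10))
  # constant series: DC removed (away from filtfilt edge transients)
  out_dc <- bandpass(toy_ts(cbind(rep(5, n)), tr = tr))$series[, 1]
  expect_lt(max(abs(out_dc[300:700])), 0.05)
  expect_lt(mean(abs(out_dc[300:700])) / 5, 0.005)
  # upper edge above Nyquist is rejected
  expect_error(bandpass(toy_ts(cbind(lo), tr = 10), f_hi = 0.08),
               "Nyquist")
})

test_that("connectivity computation matches the closed form and flags degeneracies", {
  # fixed toy series with known correlation
  set.seed(3)
  n <- 4000
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  z <- compute_fc(toy_ts(cbind(r1 = a, r2 = b)))
  expect_equal(z[1, 2], atanh(cor(a, b)), tolerance = 1e-12)
  expect_true(is.na(z[1, 1]))
  expect_equal(z[1, 2], z[2, 1])

  # independent white noise: z near 0 at the sampling scale
  w <- matrix(rnorm(n * 3), n, 3)
  zw <- compute_fc(toy_ts(w))
  expect_lt(max(abs(zw[upper.tri(zw)])), 4 / sqrt(n))

  # duplicated ROI -> infinite Fisher z -> error
  expect_error(compute_fc(toy_ts(cbind(a, a))), "perfectly correlated")
  # zero-variance ROI -> error naming it
  expect_error(compute_fc(toy_ts(cbind(konst = rep(1, 10), x = rnorm(10)))),
               "zero-variance")
})

test_that("fisher z is odd in the sign of the correlation", {
  set.seed(4)
  a <- rnorm(500)
  b <- 0.6 * a + rnorm(500, sd = 0.5)
  zp <- compute_fc(toy_ts(cbind(a, b)))[1, 2]
  zn <- compute_fc(toy_ts(cbind(a, -b)))[1, 2]
  expect_equal(zp, -zn, tolerance = 1e-12)
})

test_that("group mean connectivity averages element-wise and checks ROI sets", {
  set.seed(5)
  z1 <- compute_fc(toy_ts(matrix(rnorm(300), 100, 3)))
  expect_equal(group_mean_fc(list(z1)), z1, ignore_attr = TRUE)
  z2 <- z1
  z2[upper.tri(z2)] <- -z1[upper.tri(z1)]
  z2[lower.tri(z2)] <- t(z2)[lower.tri(z2)]
  gm <- group_mean_fc(list(z1, z2))
  expect_equal(max(abs(gm[upper.tri(gm)])), 0)
  z3 <- z1[1:2, 1:2]
  expect_error(group_mean_fc(list(z1, z3)), "mismatched")
})

test_that("time-series path converges to the generating correlation model", {
  cfg <- sim_config(n_subjects = 2, artifact_strength = 0, fd_spike_rate = 0)
  parc <- tiny_parcellation(c(Vis = 4, SAL = 3))
  subj <- data.frame(subject_id = c("S1", "S2"))
  tslist <- gen_timeseries(subj, parc, cfg, seed = 6, frames = 20000)
  z <- compute_fc(tslist[[1]])
  r <- tanh(z)
  within_vis <- r[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  between <- as.numeric(r[1:4, 5:7])
  expect_lt(abs(mean(within_vis) - cfg$mu_within), 0.03)
  expect_lt(abs(mean(between) - cfg$mu_weak), 0.03)  # SAL-Vis is the weak block
  # determinism
  tslist2 <- gen_timeseries(subj, parc, cfg, seed = 6, frames = 20000)
  expect_identical(tslist[[1]]$series, tslist2[[1]]$series)
})

test_that("simulated nuisance artifacts are removable by regression", {
  cfg <- sim_config(n_subjects = 1, artifact_strength = 0.6)
  parc <- tiny_parcellation(c(Vis = 3, SAL = 2))
  ts <- gen_timeseries(data.frame(subject_id = "S1"), parc, cfg,
                       seed = 7, frames = 3000)[[1]]
  before <- max(abs(cor(ts$series, ts$nuisance)))
  after <- max(abs(cor(nuisance_regress(ts)$series, ts$nuisance)))
  expect_gt(before, 0.2)
  expect_lt(after, 1e-10)
})

test_that("an all-spike FD trace censors every frame", {
  ts <- toy_ts(matrix(rnorm(40), 20, 2), fd = rep(0.5, 20))
  m <- censor_frames(ts, 0.2)
  expect_false(any(m$retained))
  expect_false(subject_qc(m))
  expect_error(compute_fc(ts, m), "retained frames")
})
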