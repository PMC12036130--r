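test_that("blocks partition all pairs with the expected combinatorics", {
  parc <- suppressMessages(filter_parcellation(gen_parcellation(100, seed = 1)))
  bl <- define_blocks(parc)
  expect_equal(nrow(bl$blocks), 91)  # 13 * 14 / 2
  expect_equal(sum(bl$blocks$k), 100 * 99 / 2)
  expect_equal(length(bl$pair_block), 100 * 99 / 2)
  expect_true(all(tabulate(bl$pair_block, 91) == bl$blocks$k))

  # 2 networks of sizes 3 and 2: within-A, between, within-B = 3, 6, 1
  parc2 <- tiny_parcellation(c(Vis = 3, SAL = 2))
  bl2 <- define_blocks(parc2)
  expect_setequal(bl2$blocks$k, c(3L, 6L, 1L))
  kk <- bl2$blocks
  expect_equal(kk$k[kk$net_a == "Vis" & kk$net_b == "Vis"], 3L)
  expect_equal(kk$k[kk$net_a == "Vis" & kk$net_b == "SAL"], 6L)
  expect_equal(kk$k[kk$net_a == "SAL" & kk$net_b == "SAL"], 1L)

  # single network: one block holding every pair
  parc1 <- tiny_parcellation(c(DMN = 5))
  bl1 <- define_blocks(parc1)
  expect_equal(nrow(bl1$blocks), 1)
  expect_equal(bl1$blocks$k, 10L)

  unass <- parc
  unass$network[1] <- "unassigned"
  expect_error(define_blocks(unass), "unassigned")
})

test_that("ORA proportion follows the threshold rule", {
  tv <- c(3.0, 0.1, -0.2, 2.5)
  # qt(0.975, 1e6) ~ 1.96: two of four exceed
  expect_equal(ora_stat(tv, 1:4, alpha = 0.05, df = 1e6), 0.5)
  expect_equal(ora_stat(c(0.5, -1, 0.2), 1:3, alpha = 0.05, df = 50), 0)
  expect_error(ora_stat(tv, integer(), alpha = 0.05, df = 50), "empty block")
})

test_that("hypergeometric ORA p matches exhaustive enumeration", {
  # 10 pairs, 3 exceedances, block of 4 holding all three
  df <- 40
  crit <- qt(0.975, df)
  tv <- c(3, 3.2, 2.8, 0.1, -0.3, 0.2, 0.5, -0.7, 1.0, 0.4)
  block <- 1:4
  p_fast <- ora_hypergeom_p(tv, block, alpha = 0.05, df = df)
  # enumerate all 4-subsets: P(at least q of the 3 exceedances in the block)
  ex <- abs(tv) > crit
  q <- sum(ex[block])
  combs <- combn(10, 4)
  p_enum <- mean(apply(combs, 2, function(s) sum(ex[s]) >= q))
  expect_equal(p_fast, p_enum, tolerance = 1e-12)

  # degenerate tails
  expect_equal(ora_hypergeom_p(rep(5, 6), 1:3, alpha = 0.05, df = df), 1)
  expect_equal(ora_hypergeom_p(rep(0, 6), 1:3, alpha = 0.05, df = df), 1)
})

test_that("max-mean variants evaluate their definitions", {
  s <- c(2, -1, 1, -4)
  expect_equal(maxmean_stat(s, 1:4, "efron_tibshirani"), 1.25)
  expect_equal(maxmean_stat(s, 1:4, "signed_difference"), -0.5)
  expect_equal(maxmean_stat(rep(0, 3), 1:3, "efron_tibshirani"), 0)
  expect_equal(maxmean_stat(rep(0, 3), 1:3, "signed_difference"), 0)
  expect_equal(maxmean_stat(c(3), 1, "efron_tibshirani"), 3)
  expect_equal(maxmean_stat(c(3), 1, "signed_difference"), 3)
  expect_error(maxmean_stat(s, 1:4, channel = "f"), "directional")
  # linear scaling of the statistics scales max-mean linearly
  expect_equal(maxmean_stat(2.5 * s, 1:4), 2.5 * maxmean_stat(s, 1:4))
})

test_that("GSEA enrichment score matches a direct running-sum oracle", {
  # oracle: walk the full ranking explicitly
  es_walk <- function(stats, members, weight) {
    key <- abs(stats)
    ord <- order(key, decreasing = TRUE)
    inblk <- ord %in% members
    w <- key[ord]^weight
    inc <- ifelse(inblk, w / sum(w[inblk]), 0)
    dec <- ifelse(inblk, 0, 1 / (length(stats) - length(members)))
    run <- cumsum(inc - dec)
    max(0, max(run))
  }
  set.seed(11)
  for (w in c(0, 1)) {
    tv <- rnorm(20)
    members <- c(2, 5, 8, 13, 17)
    expect_equal(gsea_stat(tv, members, weight = w), es_walk(tv, members, w),
                 tolerance = 1e-12)
  }
  # block = exactly the top-k ranked pairs: ES -> 1 at weight 1
  tv <- c(10, 9, 8, rep(0.01, 17))
  expect_gt(gsea_stat(tv, 1:3, weight = 1), 0.99)
  # uniformly interleaved members give a small ES; hand-walked value
  tv2 <- seq(20, 1)  # ranking is the identity
  members2 <- c(4, 8, 12, 16, 20)
  expect_equal(gsea_stat(tv2, members2, weight = 0),
               es_walk(tv2, members2, 0), tolerance = 1e-12)
  expect_lt(gsea_stat(tv2, members2, weight = 0), 0.25)
  expect_error(gsea_stat(rep(0, 10), 1:3), "zero")
})

test_that("permutation p-values use the add-one upper-tail estimator", {
  expect_equal(perm_pvalue(100, 1:99), 1 / 100)
  expect_equal(perm_pvalue(50, 1:99), (50 + 1) / 100)
  expect_equal(perm_pvalue(0, 1:99), 1)
})

test_that("permutation nulls are brain-wide consistent and reproducible", {
  setup <- small_screening_setup(n = 24, n_rois = 20, seed = 21)
  bl <- define_blocks(setup$parc)
  cfg <- ea_config(seed = 3)
  nn1 <- permute_null(setup$fc, setup$design, bl, cfg, B = 25,
                      record_indices = TRUE)
  nn2 <- permute_null(setup$fc, setup$design, bl, cfg, B = 25,
                      record_indices = TRUE)
  expect_identical(nn1, nn2)
  perms <- attr(nn1, "perm_indices")
  expect_equal(dim(perms), c(25, 24))
  # replaying one recorded relabeling through the screening path reproduces
  # every block's null value for that replicate (single brain-wide reshuffle)
  W <- setup$design$X[, -setup$design$idx_test]
  fitW <- qr.fitted(qr(W), setup$fc)
  resW <- setup$fc - fitW
  b <- 13
  st <- fcea:::.screen_stats(fitW + resW[perms[b, ], , drop = FALSE],
                             setup$design)
  ne <- which(bl$blocks$k > 0)
  for (stat in c("ora", "maxmean", "gsea")) {
    ref <- vapply(ne, function(g) {
      f <- switch(stat,
                  ora = ora_stat(st$t_sa, bl$idx[[g]], 0.05,
                                 setup$design$residual_df),
                  maxmean = maxmean_stat(st$t_sa, bl$idx[[g]]),
                  gsea = gsea_stat(st$t_sa, bl$idx[[g]]))
      f
    }, numeric(1))
    expect_equal(unname(nn1$t_sa[[stat]][b, ne]), ref, tolerance = 1e-10)
  }
})

test_that("permutation schemes agree under the global null distributionally", {
  setup <- small_screening_setup(n = 30, n_rois = 16, seed = 22)
  bl <- define_blocks(setup$parc)
  nn_fl <- permute_null(setup$fc, setup$design, bl,
                        ea_config(seed = 4, permutation_scheme = "freedman_lane"),
                        B = 150, channels = "t_sa", statistics = "maxmean")
  nn_js <- permute_null(setup$fc, setup$design, bl,
                        ea_config(seed = 4,
                                  permutation_scheme = "joint_behavior_shuffle"),
                        B = 150, channels = "t_sa", statistics = "maxmean")
  # same scale of null values for a mid-size block
  g <- which.max(bl$blocks$k)
  m_fl <- mean(nn_fl$t_sa$maxmean[, g])
  m_js <- mean(nn_js$t_sa$maxmean[, g])
  expect_lt(abs(m_fl - m_js) / m_fl, 0.25)
})

test_that("run_ea assembles a complete labelled table with sane p-values", {
  setup <- small_screening_setup(n = 24, n_rois = 30, seed = 23)
  bl <- define_blocks(setup$parc)
  ea <- run_ea(setup$fc, setup$design, bl, ea_config(seed = 5), B = 99)
  ne <- sum(bl$blocks$k > 0)
  # channels t_sa/t_rrb: 3 stats; f_joint: 2
  expect_equal(nrow(ea), 91 * (3 + 3 + 2))
  expect_true(all(ea$p[!is.na(ea$p)] >= 1 / 100))
  expect_true(all(ea$p[!is.na(ea$p)] <= 1))
  expect_false(any(ea$statistic == "maxmean" & ea$channel == "f_joint"))
  obs <- ea$observed[!is.na(ea$observed)]
  expect_true(all(ea$observed[ea$statistic == "ora" & !is.na(ea$observed)] >= 0))
  expect_true(all(ea$observed[ea$statistic == "ora" & !is.na(ea$observed)] <= 1))
  expect_true(all(ea$observed[ea$statistic == "gsea" & !is.na(ea$observed)] <= 1))
  expect_true(all(ea$observed[ea$statistic == "maxmean" & !is.na(ea$observed)] >= 0))
  # empty blocks give NA rows
  expect_equal(sum(is.na(ea$p[ea$statistic == "ora"])),
               (91 - ne) * 3)
})

test_that("B bounds and channel/statistic mismatches error", {
  setup <- small_screening_setup(n = 20, n_rois = 14, seed = 24)
  bl <- define_blocks(setup$parc)
  expect_error(permute_null(setup$fc, setup$design, bl, ea_config(), B = 0),
               "at least 1")
  expect_error(permute_null(setup$fc, setup$design, bl, ea_config(), B = 10,
                            channels = "f_joint", statistics = "maxmean"),
               "F screening channel")
  expect_error(ea_config(B_ora = 0), "at least 1")
  expect_error(ea_config(alpha_per_test = 0), "\\(0, 1\\)")
})

test_that("FWER calibration resolves its inputs and degenerate alphas", {
  expect_error(calibrate_fwer(B = 100, alpha_per_test = 5e-4),
               "need B >=")
  # closed form: 1 - (1 - a)^m, and the estimator runs at toy sizes
  cal <- suppressWarnings(suppressMessages(
    calibrate_fwer(n_subjects = 20, n_rois = 30, B = 60, n_datasets = 4,
                   alpha_per_test = 0.2, seed = 2)))
  expect_equal(cal$analytic, 1 - (1 - 0.2)^cal$n_blocks)
  expect_length(cal$hit, 4)
  expect_true(cal$estimate >= 0 && cal$estimate <= 1)
})
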