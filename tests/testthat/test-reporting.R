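test_that("hit identification thresholds brain-wide at strict quantiles", {
  set.seed(31)
  tv <- rnorm(40)
  h <- identify_hits(tv, tail_fraction = 0.025)
  thr <- attr(h, "thresholds")
  # quantile arithmetic: exactly one candidate per tail at 2.5% of 40
  expect_equal(sum(tv > thr["upper"]), 1)
  expect_equal(sum(tv < thr["lower"]), 1)
  expect_equal(nrow(h), 2)
  expect_setequal(h$sign, c("positive", "negative"))

  # all-zero statistics: no hits (ties excluded by strict inequality)
  expect_equal(nrow(identify_hits(rep(0, 40))), 0)
  expect_error(identify_hits(tv, tail_fraction = 0.6), "\\(0, 0.5\\)")
  expect_error(identify_hits(tv, members = integer()), "empty block")
})

test_that("hits restricted to a block use brain-wide thresholds", {
  set.seed(32)
  tv <- rnorm(200)
  members <- 1:50
  h_all <- identify_hits(tv)
  h_blk <- identify_hits(tv, members)
  expect_setequal(h_blk$pair, intersect(h_all$pair, members))
})

test_that("hit classification fills laterality and anatomy with conserved proportions", {
  parc <- tiny_parcellation(c(Vis = 4),
                            hemispheres = c("L", "R", "L", "M"),
                            anat = c("cortical", "cortical", "subcortical",
                                     "cortical"))
  pidx <- pair_index(parc)
  hits <- data.frame(pair = c(1, 2, 3, 5),
                     t = c(3, -3, 2.5, 2.7),
                     sign = c("positive", "negative", "positive", "positive"))
  hits$roi_i <- pidx$roi_i[hits$pair]
  hits$roi_j <- pidx$roi_j[hits$pair]
  cl <- classify_hits(hits, parc)
  # pair 1 = (1,2) L-R cortical/cortical
  expect_equal(cl$laterality[1], "contralateral")
  expect_equal(cl$anat[1], "cortico-cortical")
  # pair 2 = (1,3) L-L cortical/subcortical
  expect_equal(cl$laterality[2], "left")
  expect_equal(cl$anat[2], "other")
  # pair involving the midline ROI
  expect_true("midline-involved" %in% cl$laterality)
  summ <- attr(cl, "summary")
  expect_equal(sum(summ$laterality), 1)
  expect_equal(sum(summ$anat), 1)

  bad <- parc
  bad$hemisphere[1] <- "X"
  expect_error(classify_hits(hits, bad), "hemisphere")
})

test_that("planted positive coupling yields predominantly positive hits", {
  cfg <- sim_config(n_subjects = 60)
  parc <- suppressMessages(filter_parcellation(gen_parcellation(80, seed = 33)))
  coh <- gen_cohort(cfg, seed = 33)
  design <- build_design(coh$subjects, coh$behaviors)
  cfg$coupling <- list(networks = c("SAL", "Vis"), behavior = "SA",
                       slope = calibrate_slope(design, cfg, 2))
  fc <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg, seed = 33)
  bl <- define_blocks(parc)
  tb <- which(bl$blocks$net_a %in% c("SAL", "Vis") &
                bl$blocks$net_b %in% c("SAL", "Vis") &
                bl$blocks$net_a != bl$blocks$net_b)
  sc <- suppressMessages(screen_all(fc, design))
  h <- identify_hits(sc$t_sa, bl$idx[[tb]], pidx = attr(fc, "pair_index"))
  expect_gt(nrow(h), 0)
  expect_gt(mean(h$sign == "positive"), 0.8)
})

test_that("stratified summaries detect a planted shift and reject empty strata", {
  cfg <- sim_config(n_subjects = 120)
  parc <- suppressMessages(filter_parcellation(gen_parcellation(40, seed = 34)))
  coh <- gen_cohort(cfg, seed = 34)
  cfg$coupling <- list(networks = c("SAL", "Vis"), behavior = "SA",
                       slope = 0.08)
  fc <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg, seed = 34)
  bl <- define_blocks(parc)
  tb <- which(bl$blocks$net_a %in% c("SAL", "Vis") &
                bl$blocks$net_b %in% c("SAL", "Vis") &
                bl$blocks$net_a != bl$blocks$net_b)
  ss <- stratified_fc_summary(fc, coh$behaviors, bl$idx[[tb]])
  expect_gt(ss$shift, 0)
  # null: no systematic shift
  cfg0 <- sim_config(n_subjects = 120)
  fc0 <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg0, seed = 35)
  ss0 <- stratified_fc_summary(fc0, coh$behaviors, bl$idx[[tb]])
  expect_lt(abs(ss0$shift), abs(ss$shift) / 2)
  # single-stratum cohorts error by name
  beh_low <- coh$behaviors
  beh_low$SA <- 1L
  expect_error(stratified_fc_summary(fc, beh_low, bl$idx[[tb]]),
               "empty stratum")
})

test_that("matrix export orders networks with subcortical ROIs first and inverts", {
  parc <- suppressMessages(filter_parcellation(gen_parcellation(50, seed = 36)))
  v <- rnorm(50 * 49 / 2)
  ex <- export_matrix(v, parc)
  expect_equal(dim(ex$matrix), c(50, 50))
  expect_equal(nrow(ex$boundaries), 13)
  expect_equal(ex$boundaries$end[13], 50)
  # network-major ordering: each network contiguous, canonical order
  nets_in_order <- ex$boundaries$network
  expect_equal(nets_in_order,
               intersect(fcea_networks(), unique(parc$network)))
  # within a network, non-cortical ROIs come first
  b1 <- ex$boundaries[1, ]
  rois <- as.integer(rownames(ex$matrix))[b1$start:b1$end]
  cls <- parc$anat_class[match(rois, parc$roi_id)]
  expect_true(all(diff(cls == "cortical") >= 0))
  # inverse permutation restores the input
  m0 <- pairs_to_matrix(v, parc)
  inv <- order(ex$order)
  expect_equal(ex$matrix[inv, inv], m0, ignore_attr = TRUE)
  # single-network toy
  p1 <- tiny_parcellation(c(DMN = 4))
  ex1 <- export_matrix(rnorm(6), p1)
  expect_equal(nrow(ex1$boundaries), 1)
})

test_that("round-trip serialization preserves tables", {
  setup <- small_screening_setup(n = 16, n_rois = 8, seed = 37)
  sc <- suppressMessages(screen_all(setup$fc, setup$design))
  tmp <- tempfile(fileext = ".tsv")
  write_fc_pairs(setup$fc, tmp)
  back <- read_fc_pairs(tmp)
  expect_equal(unname(back), unname(setup$fc[, ]), tolerance = 1e-12)
  write_screening(sc, tmp)
  tab <- read_tsv(tmp)
  expect_equal(names(tab), c("roi_i", "roi_j", "network_i", "network_j",
                             "t_sa", "t_rrb", "f_joint", "df_den"))
  expect_equal(tab$t_sa, sc$t_sa, tolerance = 1e-12)
  unlink(tmp)
})
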