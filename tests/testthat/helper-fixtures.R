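# Small fixtures built in code for the unit tests.

# tiny filtered parcellation with a fixed network layout
tiny_parcellation <- function(sizes = c(Vis = 3, SAL = 2),
                              hemispheres = NULL, anat = NULL) {
  nets <- rep(names(sizes), times = sizes)
  R <- length(nets)
  data.frame(
    roi_id = seq_len(R),
    x = 0, y = 0, z = 0,
    hemisphere = if (is.null(hemispheres)) rep(c("L", "R"), length.out = R)
                 else hemispheres,
    anat_class = if (is.null(anat)) rep("cortical", R) else anat,
    network = nets,
    qc_pass = TRUE,
    stringsAsFactors = FALSE)
}

# small cohort with a working design (4 sites, both sexes, varying behaviors)
small_cohort <- function(n = 24, seed = 42) {
  gen_cohort(sim_config(n_subjects = n), seed = seed)
}

# a small subjects-by-pairs connectivity matrix with its design;
# small ROI counts use a compact 3-network layout
small_screening_setup <- function(n = 24, n_rois = 12, seed = 7,
                                  cfg = sim_config(n_subjects = n)) {
  parc <- if (n_rois >= 26) {
    suppressMessages(filter_parcellation(gen_parcellation(n_rois, seed = seed)))
  } else {
    a <- n_rois %/% 3
    tiny_parcellation(c(Vis = n_rois - 2 * a, DMN = a, SAL = a))
  }
  coh <- gen_cohort(cfg, seed = seed)
  fc <- gen_connectivity(coh$subjects, coh$behaviors, parc, cfg, seed = seed)
  design <- suppressWarnings(build_design(coh$subjects, coh$behaviors))
  list(parc = parc, subjects = coh$subjects, behaviors = coh$behaviors,
       fc = fc, design = design)
}

# a synthetic time-series object with controllable ingredients
toy_ts <- function(series, fd = NULL, tr = 2, nuisance = NULL,
                   subject_id = "T001") {
  series <- as.matrix(series)
  if (is.null(fd)) fd <- rep(0, nrow(series))
  structure(list(subject_id = subject_id, tr = tr, frames = nrow(series),
                 series = series, fd = fd, nuisance = nuisance),
            class = "fcea_ts")
}
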