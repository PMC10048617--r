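# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fx_panel <- function() {
  if (is.null(.fixtures$panel)) .fixtures$panel <- gf_panel()
  .fixtures$panel
}

fx_freqs <- function() {
  if (is.null(.fixtures$freqs)) {
    .fixtures$freqs <- synthetic_frequencies(fx_panel(), seed = 7)
  }
  .fixtures$freqs
}

fx_donor <- function(i = 1) {
  if (is.null(.fixtures$donors)) {
    .fixtures$donors <- sample_reference_profiles(fx_freqs(), 6, seed = 3)
  }
  .fixtures$donors[[i]]
}

# small panel for fast single-locus / few-locus engine tests
fx_panel_sub <- function(loci) {
  p <- fx_panel()
  locus_panel(tibble::as_tibble(p)[p$locus %in% loci, , drop = FALSE])
}

# a noise-free configuration: tight peaks, no stutter, no drop-in
fx_cfg_noisefree <- function(...) {
  sim_config(cv_peak = 0.01, lsae_sd = 0, drop_in_rate = 0,
             stutter = NULL, ...)
}

# stutter model with one linear back-stutter law everywhere and small
# mean SRs for the other types; used for parameter-recovery checks
fx_recovery_stutter <- function(slope = 0.02, intercept = -0.10,
                                sr_sd = 0.01) {
  panel <- fx_panel()
  entries <- purrr::map_dfr(panel$locus, function(loc) {
    dplyr::bind_rows(
      tibble::tibble(locus = loc, type = "back", form = "linear",
                     slope = slope, intercept = intercept,
                     mean_sr = NA_real_, sr_sd = sr_sd),
      tibble::tibble(locus = loc,
                     type = c("forward", "double_back", "half_back",
                              "half_forward", "minus_1p5"),
                     form = "mean", slope = 0, intercept = 0,
                     mean_sr = c(0.03, 0.02, 0.05, 0.01, 0.01),
                     sr_sd = sr_sd))
  })
  stutter_model(entries)
}

# strip every modeled stutter type (semi-continuous engine preprocessing)
fx_strip <- function(e, cfg) {
  if (is.null(cfg$stutter)) return(e)
  filter_unmodeled_stutter(e, cfg$stutter, names(stutter_offsets()))
}

# quick single-source LR for a thresholded, stutter-stripped epg
fx_sc_lr <- function(e, donor, freqs = fx_freqs(), panel = fx_panel(),
                     ...) {
  th <- freq_theta(freqs)
  suppressWarnings(semicontinuous_replicate_lr(
    e, hypothesis(donor, 0, theta = th),
    hypothesis(list(), 1, theta = th), freqs, panel, ...))
}
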