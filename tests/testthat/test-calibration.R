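test_that("analytical threshold arithmetic matches the doubling rule", {
  mk <- function(peak, trough) {
    list(baseline = tibble::tibble(dye = dye_channels(),
                                   highest_peak = peak,
                                   lowest_trough = trough))
  }
  expect_equal(estimate_analytical_threshold(list(mk(30, -5)))$at,
               rep(70, 5))
  expect_equal(estimate_analytical_threshold(list(mk(10, 10)))$at,
               rep(0, 5))
  # adding a control inside the extremes leaves the AT unchanged,
  # and a control can only raise the threshold (monotonicity)
  base <- estimate_analytical_threshold(list(mk(30, -5)))
  same <- estimate_analytical_threshold(list(mk(30, -5), mk(20, 0)))
  expect_equal(same$at, base$at)
  more <- estimate_analytical_threshold(list(mk(30, -5), mk(40, -10)))
  expect_true(all(more$at >= base$at))
  expect_error(estimate_analytical_threshold(list()), "control")
})

test_that("stutter prediction evaluates the fitted regression line", {
  sm <- stutter_model(tibble::tibble(
    locus = "D16S539", type = "back", form = "linear",
    slope = 0.0177, intercept = -0.1249, mean_sr = NA_real_))
  expect_equal(predict_sr(sm, "D16S539", "back", 11), 0.0698)
  # truncation at 0 and at the cap
  expect_equal(predict_sr(sm, "D16S539", "back", 2), 0)
  expect_equal(predict_sr(sm, "D16S539", "back", 60), 0.7)
  expect_error(predict_sr(sm, "D16S539", "sideways", 11), "unknown")
})

test_that("stutter fitting returns zero for stutter-free data and recovers slopes", {
  panel <- fx_panel()
  cfg0 <- sim_config(cv_peak = 0.2, lsae_sd = 0.05, drop_in_rate = 0,
                     stutter = NULL)
  donors <- sample_reference_profiles(fx_freqs(), 3, seed = 41)
  subs0 <- lapply(1:30, function(i) {
    simulate_subsample(list(list(profile = donors[[1 + i %% 3]],
                                 cells = 3L)), cfg0, panel,
                       seed = 9000 + i)
  })
  truths0 <- lapply(1:30, function(i) donors[[1 + i %% 3]])
  fit0 <- fit_stutter_model(subs0, truths0, panel)
  expect_true(all(fit0$form == "absent"))
  expect_equal(predict_sr(fit0, "TPOX", "back", 10), 0)

  # linear recovery within 2 fitted standard errors
  gen <- fx_recovery_stutter()
  cfg <- sim_config(stutter = gen, cv_peak = 0.2, lsae_sd = 0.05,
                    drop_in_rate = 0)
  subs <- lapply(1:120, function(i) {
    simulate_subsample(list(list(profile = donors[[1 + i %% 3]],
                                 cells = 3L)), cfg, panel,
                       seed = 9500 + i)
  })
  truths <- lapply(1:120, function(i) donors[[1 + i %% 3]])
  obs <- strpg:::collect_stutter_observations(subs, truths, panel)
  back <- obs[obs$type == "back", ]
  z <- vapply(unique(back$locus), function(loc) {
    o <- back[back$locus == loc, ]
    if (length(unique(o$parent_allele)) < 3) return(NA_real_)
    f <- stats::lm(sr ~ parent_allele, data = o)
    (stats::coef(f)[2] - 0.02) /
      stats::coef(summary(f))["parent_allele", "Std. Error"]
  }, 0)
  z <- z[!is.na(z)]
  expect_gt(length(z), 8)
  expect_gt(mean(abs(z) < 2), 0.85)
})

test_that("drop-in rate is the exact events/opportunities quotient", {
  panel <- fx_panel()
  mk_ctrl <- function(alleles, heights, id = "c") {
    peaks <- if (length(alleles)) {
      tibble::tibble(locus = "TPOX", allele = alleles, height = heights)
    } else {
      tibble::tibble(locus = character(), allele = double(),
                     height = double())
    }
    epg(peaks, sample_id = id, cell_count = 0L, at_applied = TRUE,
        panel = panel)
  }
  ctrls <- c(lapply(1:11, function(i) mk_ctrl(8, 500, paste0("c", i))),
             lapply(12:35, function(i) mk_ctrl(numeric(0), numeric(0),
                                               paste0("c", i))))
  res <- estimate_drop_in_rate(ctrls, panel)
  expect_equal(res$opportunities, 735)
  expect_equal(res$events, 11)
  expect_equal(res$rate, 11 / 735)

  # zero events
  res0 <- estimate_drop_in_rate(lapply(1:5, function(i) {
    mk_ctrl(numeric(0), numeric(0), paste0("z", i))
  }), panel)
  expect_equal(res0$rate, 0)
  expect_equal(res0$cap_suggested, 1000)

  # the 4800 -> 5000 cap suggestion
  res48 <- estimate_drop_in_rate(list(mk_ctrl(8, 4800)), panel)
  expect_equal(res48$cap_suggested, 5000)

  # contamination guard
  expect_warning(estimate_drop_in_rate(list(mk_ctrl(c(7, 8, 9, 10),
                                                    rep(100, 4)))),
                 "contamination")
  expect_error(estimate_drop_in_rate(list(), panel), "opportunities")
})

test_that("saturation is located within one bin of the true clipping point", {
  panel <- fx_panel()
  donors <- sample_reference_profiles(fx_freqs(), 4, seed = 51)
  stut <- default_stutter_model(panel)
  run <- function(saturation) {
    cfg <- sim_config(cv_peak = 1, lsae_sd = 0.2, drop_in_rate = 0,
                      stutter = stut, saturation = saturation)
    stds <- lapply(1:40, function(i) {
      simulate_subsample(list(list(profile = donors[[1 + i %% 4]],
                                   cells = 8L)), cfg, panel,
                         seed = 12000 + i)
    })
    truths <- lapply(1:40, function(i) donors[[1 + i %% 4]])
    estimate_saturation_threshold(stds, truths, stut, panel)
  }
  s30 <- run(30000)
  expect_false(is.na(s30$saturation_rfu))
  expect_lte(abs(s30$saturation_rfu - 30000), 2000)
  s10 <- run(10000)
  expect_lte(abs(s10$saturation_rfu - 10000), 2000)
  # effectively no clipping -> none detected
  shi <- run(10^7)
  expect_true(is.na(shi$saturation_rfu))
})

test_that("heterozygote balance bounds behave like a variance estimate", {
  panel <- fx_panel()
  donor <- fx_donor(5)
  # perfectly balanced: c^2 = 0, everything within bounds
  clean <- lapply(1:30, function(i) profile_to_epg(donor, panel, 1000))
  hb0 <- heterozygote_balance_bounds(clean, donor)
  expect_equal(hb0$c_squared, 0)
  expect_equal(hb0$within_bounds_fraction, 1)

  # Gaussian coverage oracle: log10 Hb ~ N(0, c2/APH) gives ~95% at 1.96
  set.seed(77)
  c2 <- 40
  aph <- stats::runif(5000, 200, 5000)
  lhb <- stats::rnorm(5000, 0, sqrt(c2 / aph))
  het_loc <- donor$locus[donor$a1 != donor$a2][1]
  g <- profile_genotype(donor, het_loc)
  sims <- lapply(seq_along(aph), function(i) {
    h1 <- 2 * aph[i] / (1 + 10^lhb[i])
    h2 <- h1 * 10^lhb[i]
    epg(tibble::tibble(locus = het_loc, allele = g, height = c(h1, h2)),
        panel = panel, at_applied = TRUE)
  })
  hb <- heterozygote_balance_bounds(sims, donor)
  expect_lt(abs(hb$c_squared - c2) / c2, 0.25)
  expect_lt(abs(hb$within_bounds_fraction - 0.95), 0.02)

  # single-cell subsampling yields broader bounds than a
  # standard-analysis-like protocol (tight per-copy variance, high
  # template) at every APH
  cfg_sc <- sim_config(drop_in_rate = 0, stutter = NULL)
  cfg_std <- sim_config(cv_peak = 0.3, lsae_sd = 0.05,
                        drop_in_rate = 0, stutter = NULL)
  subs_sc <- lapply(1:120, function(i) {
    simulate_subsample(list(list(profile = donor, cells = 1L)), cfg_sc,
                       panel, seed = 13000 + i)
  })
  subs_std <- lapply(1:120, function(i) {
    simulate_subsample(list(list(profile = donor, cells = 10L)),
                       cfg_std, panel, seed = 14000 + i)
  })
  hb_sc <- heterozygote_balance_bounds(subs_sc, donor)
  hb_std <- heterozygote_balance_bounds(subs_std, donor)
  expect_gt(hb_sc$c_squared, hb_std$c_squared)
  for (a in c(100, 1000, 10000)) {
    expect_gt(hb_sc$bounds(a), hb_std$bounds(a))
  }
  expect_error(heterozygote_balance_bounds(clean[1:3], donor,
                                           min_obs = 1000), "at least")
})
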