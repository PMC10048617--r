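test_that("theta-corrected match probabilities reduce and evaluate correctly", {
  f <- allele_freqs(tibble::tibble(locus = "TPOX",
                                   allele = c(8, 9, 10, 11),
                                   freq = c(0.1, 0.2, 0.3, 0.4)),
                    theta = 0)
  expect_equal(locus_match_probability(c(8, 9), f, "TPOX"),
               2 * 0.1 * 0.2)
  expect_equal(locus_match_probability(c(10, 10), f, "TPOX"), 0.09)
  f1 <- allele_freqs(tibble::tibble(locus = "TPOX", allele = 8,
                                    freq = 1), theta = 0)
  expect_equal(locus_match_probability(c(8, 8), f1, "TPOX"), 1)

  # direct arithmetic oracle at theta = 0.01
  th <- 0.01
  hand <- 2 * (th + (1 - th) * 0.1) * (th + (1 - th) * 0.2) /
    ((1 + th) * (1 + 2 * th))
  f2 <- allele_freqs(tibble::tibble(locus = "TPOX",
                                    allele = c(8, 9, 10, 11),
                                    freq = c(0.1, 0.2, 0.3, 0.4)),
                     theta = 0.01)
  expect_equal(locus_match_probability(c(8, 9), f2, "TPOX"), hand)
  expect_equal(round(hand, 5), 0.04401)
  expect_error(locus_match_probability(c(8, 9), f2, "D5S818"), "absent")
})

test_that("match probability rises with frequency; profile LR falls with theta", {
  set.seed(5)
  for (i in 1:20) {
    p1 <- stats::runif(1, 0.01, 0.4)
    p2 <- stats::runif(1, 0.01, 0.4)
    f_lo <- allele_freqs(tibble::tibble(locus = "TPOX",
                                        allele = c(8, 9, 10),
                                        freq = c(p1, p2,
                                                 1 - p1 - p2)),
                         theta = 0.01)
    f_hi <- allele_freqs(tibble::tibble(locus = "TPOX",
                                        allele = c(8, 9, 10),
                                        freq = c(p1 * 1.5, p2,
                                                 1 - 1.5 * p1 - p2)),
                         theta = 0.01)
    expect_gt(locus_match_probability(c(8, 9), f_hi, "TPOX"),
              locus_match_probability(c(8, 9), f_lo, "TPOX"))
  }
  prof <- fx_donor(1)
  lr0 <- single_source_profile_lr(prof, set_theta(fx_freqs(), 0))
  lr1 <- single_source_profile_lr(prof, set_theta(fx_freqs(), 0.03))
  expect_lt(lr1$log10_lr_total, lr0$log10_lr_total)
})

test_that("single-source profile LR has its closed forms", {
  f <- allele_freqs(tibble::tibble(locus = "TPOX", allele = c(8, 9),
                                   freq = c(0.5, 0.5)), theta = 0)
  prof <- ref_profile(tibble::tibble(locus = "TPOX", a1 = 8, a2 = 9))
  r <- single_source_profile_lr(prof, f)
  expect_equal(r$log10_lr_total, log10(2), tolerance = 1e-12)

  # 21 heterozygous loci with every frequency 0.1 -> 21 * log10(50)
  panel <- fx_panel()
  f21 <- allele_freqs(purrr::map_dfr(panel$locus, function(loc) {
    tibble::tibble(locus = loc, allele = seq(8, 17), freq = 0.1)
  }), theta = 0)
  prof21 <- ref_profile(tibble::tibble(locus = panel$locus, a1 = 8,
                                       a2 = 9))
  r21 <- single_source_profile_lr(prof21, f21)
  expect_equal(r21$log10_lr_total, 21 * log10(50), tolerance = 1e-9)
  expect_equal(sum(r21$per_locus$log10_lr), r21$log10_lr_total)
  expect_error(single_source_profile_lr(prof, f, loci = "D5S818"),
               "missing")
})

test_that("the semi-continuous model collapses to the hand formula", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  th <- freq_theta(freqs)
  for (i in 1:5) {
    prof <- fx_donor(i)
    clean <- profile_to_epg(prof, panel)
    hp <- hypothesis(prof, 0, theta = th)
    hd <- hypothesis(list(), 1, theta = th)
    sc <- semicontinuous_replicate_lr(clean, hp, hd, freqs, panel,
                                      d_grid = 0, dropin_rate = 0)
    hand <- single_source_profile_lr(prof, freqs)
    expect_equal(sc$log10_lr_total, hand$log10_lr_total,
                 tolerance = 1e-9)
    # duplicating an identical noiseless replicate changes nothing
    sc2 <- semicontinuous_replicate_lr(list(clean, clean), hp, hd,
                                       freqs, panel, d_grid = 0,
                                       dropin_rate = 0)
    expect_equal(sc2$log10_lr_total, sc$log10_lr_total,
                 tolerance = 1e-9)
  }
})

test_that("one-locus drop-out case matches brute-force enumeration", {
  # donor {8, 9}, freq(8) = freq(9) = 0.1, observed {8} only,
  # d fixed at 0.3, no drop-in, theta = 0
  alleles <- c(8, 9, 10, 11, 12)
  fr <- c(0.1, 0.1, 0.3, 0.3, 0.2)
  f <- allele_freqs(tibble::tibble(locus = "TPOX", allele = alleles,
                                   freq = fr), theta = 0)
  panel <- fx_panel_sub("TPOX")
  prof <- ref_profile(tibble::tibble(locus = "TPOX", a1 = 8, a2 = 9))
  obs <- epg(tibble::tibble(locus = "TPOX", allele = 8, height = 500),
             panel = panel, at_applied = TRUE)
  d <- 0.3
  # independent enumeration over all unordered genotypes
  hd_lik <- 0
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    prior <- if (i == j) fr[i]^2 else 2 * fr[i] * fr[j]
    g <- c(alleles[i], alleles[j])
    p_obs <- if (!8 %in% g) 0
    else if (g[1] == 8 && g[2] == 8) 1 - d^2
    else (1 - d) * d   # 8 detected, the other allele dropped
    hd_lik <- hd_lik + prior * p_obs
  }
  hp_lik <- (1 - d) * d
  hand_lr <- log10(hp_lik / hd_lik)
  res <- semicontinuous_replicate_lr(
    obs, hypothesis(prof, 0, theta = 0),
    hypothesis(list(), 1, theta = 0), f, panel, d_grid = d,
    dropin_rate = 0, loci = "TPOX")
  expect_equal(res$log10_lr_total, hand_lr, tolerance = 1e-9)
})

test_that("log10 LR is invariant to locus and replicate ordering", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  cfg <- sim_config()
  prof <- fx_donor(2)
  e1 <- fx_strip(simulate_subsample(list(list(profile = prof,
                                              cells = 2L)),
                                    cfg, panel, seed = 101), cfg)
  e2 <- fx_strip(simulate_subsample(list(list(profile = prof,
                                              cells = 1L)),
                                    cfg, panel, seed = 102), cfg)
  th <- freq_theta(freqs)
  hp <- hypothesis(prof, 0, theta = th)
  hd <- hypothesis(list(), 1, theta = th)
  a <- suppressWarnings(
    semicontinuous_replicate_lr(list(e1, e2), hp, hd, freqs, panel))
  b <- suppressWarnings(
    semicontinuous_replicate_lr(list(e2, e1), hp, hd, freqs, panel))
  expect_equal(a$log10_lr_total, b$log10_lr_total, tolerance = 1e-9)
  c_ <- suppressWarnings(
    semicontinuous_replicate_lr(list(e1, e2), hp, hd, freqs, panel,
                                loci = rev(panel$locus)))
  expect_equal(sort(a$per_locus$log10_lr), sort(c_$per_locus$log10_lr),
               tolerance = 1e-9)
})

test_that("semi-continuous locus likelihoods are proper probabilities", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  cfg <- sim_config()
  prof <- fx_donor(3)
  e <- fx_strip(simulate_subsample(list(list(profile = prof,
                                             cells = 1L)),
                                   cfg, panel, seed = 103), cfg)
  th <- freq_theta(freqs)
  for (hyp in list(hypothesis(prof, 0, theta = th),
                   hypothesis(list(), 1, theta = th))) {
    obs <- lapply(list(e), function(ee) {
      lapply(stats::setNames(panel$locus, panel$locus),
             function(loc) ee$allele[ee$locus == loc])
    })
    for (loc in panel$locus[1:8]) {
      scen <- strpg:::build_sc_scenario(
        loc, lapply(obs, function(o) o[[loc]]), hyp,
        hypothesis(prof, 0, theta = th),
        hypothesis(list(), 1, theta = th), freqs, 0.0164, 2)
      lik <- strpg:::sc_locus_lik(scen, matrix(0.3, nrow = hyp$noc))
      expect_gte(lik, 0)
      expect_lte(lik, 1 + 1e-12)
    }
  }
})

test_that("complementary drop-out replicates beat either replicate alone", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  prof <- fx_donor(1)
  clean <- profile_to_epg(prof, panel, height = 1500)
  loc <- prof$locus[prof$a1 != prof$a2][2]
  g <- profile_genotype(prof, loc)
  drop_one <- function(a) {
    pk <- tibble::as_tibble(clean)
    epg(pk[!(pk$locus == loc & pk$allele == a), ], sample_id = "r",
        at_applied = TRUE)
  }
  r1 <- drop_one(g[2])
  r2 <- drop_one(g[1])
  l1 <- fx_sc_lr(r1, prof)$log10_lr_total
  l2 <- fx_sc_lr(r2, prof)$log10_lr_total
  joint <- fx_sc_lr(list(r1, r2), prof)$log10_lr_total
  expect_gt(joint, l1)
  expect_gt(joint, l2)
})

test_that("database search is consistent and ordered", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  prof <- fx_donor(4)
  db <- c(sample_reference_profiles(freqs, 5, seed = 61, prefix = "NC"),
          list(prof))
  clean <- profile_to_epg(prof, panel)
  hits <- database_search(clean, db, freqs, panel)
  expect_equal(hits$donor_id,
               sort(vapply(db, profile_donor_id, "")))
  direct <- fx_sc_lr(clean, prof)
  expect_equal(hits$log10_lr[hits$donor_id == profile_donor_id(prof)],
               direct$log10_lr_total)
  expect_error(database_search(clean, list(), freqs, panel), "empty")
})

test_that("quantitative engine agrees with the semi-continuous limit", {
  freqs <- fx_freqs()
  panel <- fx_panel()
  prof <- fx_donor(5)
  th <- freq_theta(freqs)
  hp <- hypothesis(prof, 0, theta = th)
  hd <- hypothesis(list(), 1, theta = th)
  loci <- panel$locus[1:6]
  clean <- profile_to_epg(prof, panel, height = 1500, loci = loci)
  q <- quantitative_replicate_lr(clean, hp, hd, freqs, panel,
                                 loci = loci, seed = 4)
  sc <- semicontinuous_replicate_lr(clean, hp, hd, freqs, panel,
                                    d_grid = 0.001, dropin_rate = 0.0164,
                                    loci = loci)
  expect_equal(q$status, "ok")
  expect_lt(abs(q$log10_lr_total - sc$log10_lr_total), 0.5)

  # identical hypotheses give log10 LR of exactly zero
  q0 <- quantitative_replicate_lr(clean, hp, hp, freqs, panel,
                                  loci = loci, seed = 4)
  expect_equal(q0$log10_lr_total, 0)
  # contributor guard
  expect_error(quantitative_replicate_lr(
    clean, hypothesis(prof, 2, theta = th), hd, freqs, panel),
    "at most 2")
  expect_error(semicontinuous_replicate_lr(
    clean, hypothesis(prof, 3, theta = th), hd, freqs, panel),
    "at most 3")
})

test_that("mean LR over non-contributor data is one (Turing check, small)", {
  # scaled-down version of the expectation identity E[LR | Hd] = 1
  freqs <- fx_freqs()
  loc <- "D18S51"
  panel <- fx_panel_sub(loc)
  prof <- fx_donor(1)
  th <- freq_theta(freqs)
  hp <- hypothesis(prof, 0, theta = th)
  hd <- hypothesis(list(), 1, theta = th)
  d0 <- 0.3; c0 <- 0.02
  al <- freqs$allele[freqs$locus == loc]
  pr <- freqs$freq[freqs$locus == loc]
  poi_g <- profile_genotype(prof, loc)
  set.seed(909)
  lrs <- replicate(1500, {
    cnt <- table(factor(poi_g, levels = al))
    p1 <- (as.numeric(cnt) * th + (1 - th) * pr) / (1 + th)
    a1 <- sample(al, 1, prob = p1)
    cnt[as.character(a1)] <- cnt[as.character(a1)] + 1
    p2 <- (as.numeric(cnt) * th + (1 - th) * pr) / (1 + 2 * th)
    a2 <- sample(al, 1, prob = p2)
    seen <- c(a1, a2)[stats::runif(2) > d0]
    if (stats::runif(1) < c0) seen <- c(seen, sample(al, 1, prob = pr))
    seen <- unique(seen)
    pk <- if (length(seen)) {
      tibble::tibble(locus = loc, allele = seen, height = 1000,
                     size = NA_real_)
    } else {
      tibble::tibble(locus = character(), allele = double(),
                     height = double(), size = double())
    }
    e <- epg(pk, at_applied = TRUE)
    r <- semicontinuous_replicate_lr(e, hp, hd, freqs, panel,
                                     d_grid = d0, dropin_rate = c0,
                                     loci = loc)
    10^r$log10_lr_total
  })
  se <- stats::sd(lrs) / sqrt(length(lrs))
  expect_lt(abs(mean(lrs) - 1), 3 * se)
})
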