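test_that("genotype tables round-trip through both dialects", {
  panel <- fx_panel()
  cfg <- sim_config()
  epgs <- lapply(1:50, function(i) {
    simulate_subsample(list(list(profile = fx_donor(1 + i %% 3),
                                 cells = sample(1:3, 1))),
                       cfg, panel, seed = 500 + i,
                       sample_id = sprintf("s%02d", i))
  })
  for (dialect in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_genotype_table(epgs, path, dialect = dialect)
    back <- read_genotype_table(path, panel)
    expect_length(back, 50)
    for (e in epgs) {
      b <- back[[epg_sample_id(e)]]
      expect_equal(b$locus, e$locus)
      expect_equal(b$allele, e$allele)
      expect_equal(b$height, e$height)
      expect_equal(b$size, e$size)
    }
  }
})

test_that("a small wide table parses into peaks and empty loci", {
  panel <- fx_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample Name,Marker,Allele 1,Allele 2,Height 1,Height 2,Size 1,Size 2",
               "samp1,D16S539,11,12,1500,900,256,260"), path)
  epgs <- read_genotype_table(path, panel)
  expect_length(epgs, 1)
  e <- epgs[["samp1"]]
  expect_equal(nrow(epg_locus_peaks(e, "D16S539")), 2)
  expect_equal(sum(e$locus != "D16S539"), 0)
  expect_equal(nrow(epg_locus_peaks(e, "TPOX")), 0)
})

test_that("genotype reader rejects unknown markers and ragged rows", {
  panel <- fx_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample Name,Marker,Allele 1,Allele 2,Height 1,Height 2",
               "s1,NOTALOCUS,11,12,100,200"), path)
  expect_error(read_genotype_table(path, panel), "NOTALOCUS")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample Name,Marker,Allele 1,Allele 2,Height 1,Height 2",
               "s1,TPOX,11,12,100,NA"), path2)
  expect_error(read_genotype_table(path2, panel), "row 1")
})

test_that("an empty genotype table yields an empty list", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,locus,allele,height,size", path)
  expect_identical(read_genotype_table(path, fx_panel()), list())
})

test_that("frequency tables validate sums, ranges and duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus,allele,freq", "TPOX,8,0.2", "TPOX,9,0.3",
               "TPOX,10,0.5"), path)
  f <- read_frequency_table(path)
  expect_s3_class(f, "allele_freqs")
  expect_equal(sum(f$freq), 1)
  expect_equal(freq_theta(f), 0.01)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus,allele,freq", "TPOX,8,0.4", "TPOX,9,0.5"), bad)
  expect_error(read_frequency_table(bad), "TPOX")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus,allele,freq", "TPOX,8,0.5", "TPOX,8,0.5"), dup)
  expect_error(read_frequency_table(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locus,allele,freq", "TPOX,8,0", "TPOX,9,1.0"), neg)
  expect_error(read_frequency_table(neg), "frequencies")
})

test_that("unseen alleles get the 5/(2N) minimum frequency", {
  f <- allele_freqs(tibble::tibble(locus = "TPOX", allele = c(8, 9),
                                   freq = c(0.4, 0.6)), db_size = 1000)
  expect_equal(allele_freq(f, "TPOX", 11), 5 / 2000)
  f2 <- allele_freqs(tibble::tibble(locus = "TPOX", allele = c(8, 9),
                                    freq = c(0.4, 0.6)), db_size = 200)
  expect_equal(allele_freq(f2, "TPOX", 11), 5 / 400)
  expect_equal(allele_freq(f, "TPOX", 8), 0.4)
})

test_that("analytical threshold keeps boundary peaks and is idempotent", {
  panel <- fx_panel()
  at <- at_thresholds()
  e <- epg(tibble::tibble(locus = "D16S539", allele = c(11, 12),
                          height = c(52, 53)), panel = panel)
  out <- apply_analytical_threshold(e, at, panel)
  expect_equal(out$allele, 12)
  expect_equal(out$height, 53)
  expect_true(epg_at_applied(out))
  # input untouched
  expect_equal(nrow(e), 2)
  # idempotent
  expect_equal(tibble::as_tibble(apply_analytical_threshold(out, at,
                                                            panel)),
               tibble::as_tibble(out))
  # all peaks above -> identity; 1-RFU threshold removes nothing
  e2 <- simulate_subsample(fx_donor(1), sim_config(), panel, seed = 9)
  at1 <- at_thresholds(Blue = 1e-9, Green = 1e-9, Yellow = 1e-9,
                       Red = 1e-9, Purple = 1e-9)
  expect_equal(nrow(apply_analytical_threshold(e2, at1, panel)), nrow(e2))
  expect_error(apply_analytical_threshold(e, at_vectorless <- NULL,
                                          panel))
})

test_that("unmodeled stutter filtering follows position and cap rules", {
  panel <- fx_panel()
  sm <- default_stutter_model(panel)
  base <- tibble::tibble(locus = "D16S539", allele = c(16, 14),
                         height = c(10000, 1200))
  e <- epg(base, panel = panel, at_applied = TRUE)
  out <- filter_unmodeled_stutter(e, sm, "double_back")
  expect_equal(out$allele, 16)   # ratio 0.12 <= cap 0.3 -> removed

  e2 <- epg(dplyr::mutate(base, height = c(10000, 5000)), panel = panel,
            at_applied = TRUE)
  out2 <- filter_unmodeled_stutter(e2, sm, "double_back")
  expect_equal(sort(out2$allele), c(14, 16))  # ratio 0.5 > cap -> kept

  expect_equal(nrow(filter_unmodeled_stutter(e, sm, character(0))),
               nrow(e))
  expect_error(filter_unmodeled_stutter(e, sm, "sideways"), "unknown")
})

test_that("stutter filtering never removes a peak without a larger parent", {
  panel <- fx_panel()
  cfg <- sim_config()
  for (i in 1:10) {
    e <- simulate_subsample(list(list(profile = fx_donor(1 + i %% 3),
                                      cells = 2L)),
                            cfg, panel, seed = 700 + i)
    out <- filter_unmodeled_stutter(e, cfg$stutter,
                                    names(stutter_offsets()))
    removed <- dplyr::anti_join(tibble::as_tibble(e),
                                tibble::as_tibble(out),
                                by = c("locus", "allele"))
    if (nrow(removed) > 0) {
      for (r in seq_len(nrow(removed))) {
        peers <- e$height[e$locus == removed$locus[r]]
        expect_true(any(peers > removed$height[r]))
      }
    }
  }
})

test_that("panel invariants hold and sizes follow the affine mapping", {
  panel <- fx_panel()
  expect_equal(nrow(panel), 21)
  expect_false(anyDuplicated(panel$locus) > 0)
  expect_setequal(unique(panel$dye), dye_channels())
  expect_equal(sum(panel$simple), 7)
  expect_equal(allele_size(panel, "D16S539", 11),
               panel$base_bp[panel$locus == "D16S539"] + 4 * 11)
  expect_error(allele_size(panel, "NOPE", 10), "NOPE")
  bad <- tibble::as_tibble(panel)
  bad$dye[1] <- "Pink"
  expect_error(locus_panel(bad), "Pink")
})

test_that("simulation configurations round-trip through the run file", {
  cfg <- sim_config(drop_in_rate = 0.03, saturation = 12000,
                    inhibition = c(D21S11 = 0.6))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$drop_in_rate, 0.03)
  expect_equal(back$saturation, 12000)
  expect_equal(back$inhibition, c(D21S11 = 0.6))
  expect_equal(tibble::as_tibble(back$stutter),
               tibble::as_tibble(cfg$stutter))
  expect_equal(back$at$at, cfg$at$at)
  # simulation under the round-tripped config is identical
  e1 <- simulate_subsample(fx_donor(1), cfg, fx_panel(), seed = 5)
  e2 <- simulate_subsample(fx_donor(1), back, fx_panel(), seed = 5)
  expect_equal(tibble::as_tibble(e1), tibble::as_tibble(e2))
})
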