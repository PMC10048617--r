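#' Simulation configuration
#'
#' Parameters of the synthetic low-template electropherogram generator.
#' Defaults emulate 1-5 cell subsamples amplified at 32 cycles on a
#' five-dye 21-locus panel with saturation clipping at 30,000 RFU:
#'
#' * `mean_height_per_cell`: expected RFU contributed per allele copy per
#'   cell at the reference fragment size (default 2000).
#' * `cv_peak`: coefficient of variation of a single cell's per-copy
#'   amplified height (log-normal law). The default (12) is intentionally
#'   extreme: single-copy PCR at 32 cycles produces heavy-tailed heights,
#'   which makes allele drop-out *emergent* (a realised height below the
#'   dye's analytical threshold) and reproduces the extreme heterozygote
#'   imbalance seen in single-cell work. Variance shrinks as cells are
#'   added because per-cell contributions sum independently.
#' * `lsae_sd`: sd of the per-locus log amplification efficiency factor
#'   (mean-one log-normal shared by all peaks of a locus in a subsample).
#' * `stutter`: a [stutter_model()] driving simulated stutter peaks
#'   (`NULL` disables stutter generation entirely).
#' * `drop_in_rate`: per-locus per-sample probability of a drop-in peak.
#' * `drop_in_lambda`: rate of the truncated-exponential drop-in height law
#'   (RFU^-1) above the lowest dye threshold; `drop_in_unif = TRUE` swaps
#'   in a uniform height law on (floor, cap], the distribution used for
#'   drop-in rate modeling.
#' * `drop_in_cap`: ceiling of drop-in heights (default 5000 RFU).
#' * `degradation`: per-donor decay factor per 100 bp relative to
#'   `size_ref` (1 = no degradation).
#' * `inhibition`: named numeric vector of per-locus height multipliers in
#'   (0, 1].
#' * `saturation`: detector ceiling; no simulated height exceeds it.
#' * `at`: the [at_thresholds()] applied by the generator (drop-out is a
#'   height below the dye threshold).
#' * `baseline_sd`, `baseline_points`: Gaussian baseline-noise sd and the
#'   number of scan points summarised per dye in negative controls.
#'
#' @param mean_height_per_cell,cv_peak,lsae_sd,stutter,drop_in_rate
#'   See details.
#' @param drop_in_lambda,drop_in_unif,drop_in_cap,degradation,size_ref
#'   See details.
#' @param inhibition,saturation,at,baseline_sd,baseline_points See details.
#' @param cycles_note Free-text description of the amplification protocol.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_height_per_cell = 2000,
                       cv_peak = 12,
                       lsae_sd = 0.3,
                       stutter = default_stutter_model(),
                       drop_in_rate = 0.0164,
                       drop_in_lambda = 0.001,
                       drop_in_unif = FALSE,
                       drop_in_cap = 5000,
                       degradation = 1,
                       size_ref = 125,
                       inhibition = NULL,
                       saturation = 30000,
                       at = at_thresholds(),
                       baseline_sd = 5,
                       baseline_points = 500,
                       cycles_note = "32-cycle low-volume amplification") {
  stopifnot(mean_height_per_cell > 0, cv_peak > 0, lsae_sd >= 0,
            drop_in_rate >= 0, drop_in_rate <= 1,
            drop_in_cap > 0, saturation > 0,
            degradation > 0, degradation <= 1)
  if (!is.null(inhibition) &&
      (any(inhibition <= 0) || any(inhibition > 1))) {
    stop("inhibition multipliers must lie in (0, 1]")
  }
  structure(list(mean_height_per_cell = mean_height_per_cell,
                 cv_peak = cv_peak, lsae_sd = lsae_sd, stutter = stutter,
                 drop_in_rate = drop_in_rate,
                 drop_in_lambda = drop_in_lambda,
                 drop_in_unif = drop_in_unif, drop_in_cap = drop_in_cap,
                 degradation = degradation, size_ref = size_ref,
                 inhibition = inhibition, saturation = saturation,
                 at = at, baseline_sd = baseline_sd,
                 baseline_points = baseline_points,
                 cycles_note = cycles_note),
            class = "sim_config")
}

#' Derive child seeds deterministically from an experiment seed
#'
#' @param seed Parent integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Sample reference profiles from a frequency table
#'
#' Genotypes are drawn per locus under Hardy-Weinberg equilibrium,
#' independently across loci. Used to emulate known non-contributor
#' databases and simulated donors.
#'
#' @param freqs An `allele_freqs` table.
#' @param n Number of profiles.
#' @param seed RNG seed.
#' @param prefix Donor-id prefix.
#' @return A list of `ref_profile` objects.
#' @export
sample_reference_profiles <- function(freqs, n, seed = 1, prefix = "D") {
  stopifnot(n >= 1)
  set.seed(seed)
  loci <- unique(freqs$locus)
  per_locus <- lapply(loci, function(loc) {
    al <- freqs$allele[freqs$locus == loc]
    fr <- freqs$freq[freqs$locus == loc]
    if (length(al) == 0) stop("empty locus in frequency table: ", loc)
    list(al = al, fr = fr / sum(fr))
  })
  names(per_locus) <- loci
  lapply(seq_len(n), function(i) {
    g <- purrr::map_dfr(loci, function(loc) {
      pl <- per_locus[[loc]]
      draw <- pl$al[sample.int(length(pl$al), 2, replace = TRUE,
                               prob = pl$fr)]
      tibble::tibble(locus = loc, a1 = min(draw), a2 = max(draw))
    })
    ref_profile(g, donor_id = sprintf("%s%04d", prefix, i))
  })
}

# one log-normal per-copy height with mean m and cv v
rlnorm_mean_cv <- function(n, m, v) {
  sdlog <- sqrt(log(1 + v^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a cell-subsample electropherogram
#'
#' Generates one EPG from one or more donors' reference profiles. Each
#' allele copy in each cell contributes an independent log-normal height
#' with mean `mean_height_per_cell` (modulated by the locus amplification
#' efficiency factor, per-donor degradation at the allele's fragment size,
#' and any per-locus inhibition multiplier) and coefficient of variation
#' `cv_peak`; shared alleles sum contributions. Stutter peaks of all
#' modeled types are generated from the configured stutter model with
#' truncated-Gaussian ratio noise. Drop-in peaks are added per locus at
#' `drop_in_rate`. All heights are clipped at `saturation`, and any peak
#' below its dye's analytical threshold drops out. Ground-truth donor ids
#' are recorded on the result.
#'
#' @param donors A list of `list(profile = ref_profile, cells = integer)`
#'   entries (a bare `ref_profile` is treated as one donor; its `cells`
#'   defaults to 1).
#' @param cfg A [sim_config()].
#' @param panel A `locus_panel`.
#' @param seed RNG seed.
#' @param sample_id Sample identifier.
#' @param degradation Optional per-donor degradation override (vector
#'   recycled over donors); defaults to `cfg$degradation`.
#' @return A thresholded `epg` with truth metadata.
#' @export
simulate_subsample <- function(donors, cfg = sim_config(),
                               panel = gf_panel(), seed = 1,
                               sample_id = "sim", degradation = NULL) {
  if (inherits(donors, "ref_profile")) {
    donors <- list(list(profile = donors, cells = 1L))
  }
  donors <- lapply(donors, function(d) {
    if (inherits(d, "ref_profile")) list(profile = d, cells = 1L) else d
  })
  cells <- vapply(donors, function(d) as.numeric(d$cells), 0)
  if (any(cells < 0)) stop("negative cell count")
  if (is.null(degradation)) degradation <- cfg$degradation
  degradation <- rep_len(degradation, length(donors))
  set.seed(seed)
  atv <- at_vector(cfg$at)
  truth <- vapply(donors, function(d) profile_donor_id(d$profile), "")

  peaks <- vector("list", nrow(panel))
  for (li in seq_len(nrow(panel))) {
    loc <- panel$locus[li]
    lsae <- exp(stats::rnorm(1, -cfg$lsae_sd^2 / 2, cfg$lsae_sd))
    inhib <- if (!is.null(cfg$inhibition) && loc %in% names(cfg$inhibition)) {
      cfg$inhibition[[loc]]
    } else 1
    # accumulate true-allele heights
    h <- numeric(0); al <- numeric(0)
    for (k in seq_along(donors)) {
      if (cells[k] == 0) next
      g <- profile_genotype(donors[[k]]$profile, loc)
      for (a in g) {   # one entry per copy; homozygotes appear twice
        sz <- allele_size(panel, loc, a)
        m <- cfg$mean_height_per_cell * lsae * inhib *
          degradation[k]^((sz - cfg$size_ref) / 100)
        contrib <- sum(rlnorm_mean_cv(cells[k], m, cfg$cv_peak))
        j <- match(a, al)
        if (is.na(j)) { al <- c(al, a); h <- c(h, contrib) }
        else h[j] <- h[j] + contrib
      }
    }
    # stutter from each parent peak (pre-clipping heights)
    s_al <- numeric(0); s_h <- numeric(0)
    if (length(al) > 0 && !is.null(cfg$stutter)) {
      for (tp in names(stutter_offsets())) {
        sr0 <- predict_sr(cfg$stutter, loc, tp, al)
        row <- cfg$stutter[cfg$stutter$locus == loc &
                             cfg$stutter$type == tp, , drop = FALSE]
        noise_sd <- if (nrow(row) > 0 && !is.na(row$sr_sd[1])) {
          row$sr_sd[1]
        } else 0
        cap <- attr(cfg$stutter, "caps")[[tp]]
        sr <- pmin(pmax(sr0 + stats::rnorm(length(al), 0, noise_sd), 0), cap)
        pos <- stutter_position(al, tp)
        keep <- sr > 0
        s_al <- c(s_al, pos[keep])
        s_h <- c(s_h, (sr * h)[keep])
      }
    }
    # merge stutter into the allele table (stacking onto shared positions)
    for (j in seq_along(s_al)) {
      i2 <- match(s_al[j], al)
      if (is.na(i2)) { al <- c(al, s_al[j]); h <- c(h, s_h[j]) }
      else h[i2] <- h[i2] + s_h[j]
    }
    # drop-in
    if (stats::runif(1) < cfg$drop_in_rate) {
      cand <- setdiff(seq(panel$allele_min[li], panel$allele_max[li]), al)
      if (length(cand) > 0) {
        a_in <- if (length(cand) == 1) cand else sample(cand, 1)
        floor_h <- atv[[panel$dye[li]]]
        h_in <- if (isTRUE(cfg$drop_in_unif)) {
          stats::runif(1, floor_h, cfg$drop_in_cap)
        } else {
          min(floor_h + stats::rexp(1, cfg$drop_in_lambda), cfg$drop_in_cap)
        }
        al <- c(al, a_in); h <- c(h, h_in)
      }
    }
    if (length(al) > 0) {
      h <- pmin(h, cfg$saturation)
      keep <- h >= atv[[panel$dye[li]]]
      peaks[[li]] <- tibble::tibble(locus = loc, allele = al[keep],
                                    height = h[keep],
                                    size = allele_size(panel, loc,
                                                       al[keep]))
    }
  }
  epg(dplyr::bind_rows(peaks), sample_id = sample_id,
      cell_count = sum(cells), truth = truth, at_applied = TRUE,
      panel = panel)
}

#' Simulate a negative control
#'
#' A zero-cell collection or amplification blank: per dye, the highest
#' baseline peak and lowest trough over `baseline_points` Gaussian noise
#' scan points, plus any allelic drop-in peaks (which are themselves
#' subject to the analytical threshold). Supports analytical-threshold and
#' drop-in rate estimation.
#'
#' @inheritParams simulate_subsample
#' @return A list of class `noise_record` with elements `baseline` (tibble
#'   `dye`, `highest_peak`, `lowest_trough`) and `epg` (drop-in peaks as a
#'   thresholded zero-cell `epg`).
#' @export
simulate_negative_control <- function(cfg = sim_config(),
                                      panel = gf_panel(), seed = 1,
                                      sample_id = "neg") {
  set.seed(seed)
  dyes <- dye_channels()
  baseline <- purrr::map_dfr(dyes, function(d) {
    x <- if (cfg$baseline_sd > 0) {
      stats::rnorm(cfg$baseline_points, 0, cfg$baseline_sd)
    } else rep(0, cfg$baseline_points)
    tibble::tibble(dye = d, highest_peak = max(x), lowest_trough = min(x))
  })
  e <- simulate_subsample(list(), cfg, panel,
                          seed = derive_seeds(seed, 1),
                          sample_id = sample_id)
  structure(list(baseline = baseline, epg = e, sample_id = sample_id),
            class = "noise_record")
}

#' Artificially perturb a profile
#'
#' Applies the three validation perturbations used to stress-test fitted
#' genotyping parameters:
#'
#' * `degrade`: peak heights of high-molecular-weight alleles (fragment
#'   size above `size_split`) are reduced by 80% and low-molecular-weight
#'   alleles by 5%;
#' * `inhibit`: peak heights at the named loci (default D22S1045, D21S11,
#'   D13S317, D2S1338) are reduced by 40%;
#' * `drop_in`: a spurious allele (default allele 8 at D5S818) is inserted
#'   at 15,000 RFU.
#'
#' @param x A thresholded `epg`.
#' @param mode One of `"degrade"`, `"inhibit"`, `"drop_in"`.
#' @param panel A `locus_panel`.
#' @param size_split bp boundary between low and high molecular weight
#'   (default 220).
#' @param high_factor,low_factor Degradation multipliers (defaults 0.20
#'   and 0.95).
#' @param inhibit_loci,inhibit_factor Inhibited loci and multiplier
#'   (default 0.60).
#' @param drop_in_locus,drop_in_allele,drop_in_height Drop-in insertion
#'   parameters.
#' @return A new perturbed `epg`.
#' @export
perturb_profile <- function(x, mode = c("degrade", "inhibit", "drop_in"),
                            panel = gf_panel(), size_split = 220,
                            high_factor = 0.20, low_factor = 0.95,
                            inhibit_loci = c("D22S1045", "D21S11",
                                             "D13S317", "D2S1338"),
                            inhibit_factor = 0.60,
                            drop_in_locus = "D5S818", drop_in_allele = 8,
                            drop_in_height = 15000) {
  mode <- match.arg(mode)
  pk <- tibble::as_tibble(x)
  if (mode == "degrade") {
    high <- pk$size > size_split
    pk$height <- pk$height * ifelse(high, high_factor, low_factor)
  } else if (mode == "inhibit") {
    hit <- pk$locus %in% inhibit_loci
    pk$height[hit] <- pk$height[hit] * inhibit_factor
  } else {
    already <- pk$locus == drop_in_locus & pk$allele == drop_in_allele
    if (any(already)) {
      stop("drop-in allele already present at ", drop_in_locus,
           "; it would merge with a true peak, not drop in")
    }
    pk <- dplyr::bind_rows(pk, tibble::tibble(
      locus = drop_in_locus, allele = drop_in_allele,
      height = drop_in_height,
      size = allele_size(panel, drop_in_locus, drop_in_allele)))
  }
  epg_replace_peaks(x, pk)
}
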