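#' Estimate analytical thresholds from negative controls
#'
#' Per dye, `AT = 2 * (highest peak - lowest trough)`, where the highest
#' peak is the maximum baseline peak over all controls and the lowest
#' trough the minimum trough. Adding a control can only raise (or keep)
#' the threshold.
#'
#' @param controls A list of `noise_record` objects from
#'   [simulate_negative_control()] (or any list whose `baseline` element
#'   has columns `dye`, `highest_peak`, `lowest_trough`).
#' @return An `at_thresholds` tibble.
#' @export
estimate_analytical_threshold <- function(controls) {
  if (length(controls) == 0) stop("at least one negative control required")
  base <- purrr::map_dfr(controls, function(cc) cc$baseline)
  missing <- setdiff(dye_channels(), unique(base$dye))
  if (length(missing) > 0) {
    stop("dye(s) unrepresented in controls: ",
         paste(missing, collapse = ", "))
  }
  at <- base |>
    dplyr::group_by(.data$dye) |>
    dplyr::summarise(at = 2 * (max(.data$highest_peak) -
                                 min(.data$lowest_trough)),
                     .groups = "drop")
  atv <- stats::setNames(at$at, at$dye)[dye_channels()]
  structure(tibble::tibble(dye = dye_channels(), at = unname(atv)),
            class = c("at_thresholds", class(tibble::tibble())))
}

#' Fit stutter-ratio regressions from single-source subsamples
#'
#' For each locus and stutter type, stutter ratios
#' `SR = stutter height / parent allele height` are collected from
#' subsamples with known single-source truth, using only parent alleles
#' whose stutter position is not shared with a true allele of the donor
#' (composite peaks are excluded) and, for heterozygotes, not shared with
#' the sister allele's stutter of the same type. A linear least-squares
#' regression of SR on parent allele number is fitted when at least
#' `min_alleles` distinct parent alleles are available and the slope is
#' significant at `p_linear`; otherwise the mean SR is used. Entries
#' without usable observations are marked absent and predictions fall back
#' to the panel-wide mean for the type.
#'
#' @param subsamples List of thresholded `epg` objects.
#' @param truths List of `ref_profile` objects, parallel to `subsamples`
#'   (or a single profile used for all).
#' @param panel A `locus_panel`.
#' @param caps Per-type maximum-SR caps.
#' @param min_alleles Minimum distinct parent alleles for a linear fit
#'   (default 3).
#' @param p_linear Slope significance level switching linear vs mean
#'   (default 0.05).
#' @param allele_tol Position-matching tolerance in repeat units.
#' @return A `stutter_model`.
#' @export
fit_stutter_model <- function(subsamples, truths, panel = gf_panel(),
                              caps = default_stutter_caps(),
                              min_alleles = 3, p_linear = 0.05,
                              allele_tol = 0.05) {
  if (inherits(truths, "ref_profile")) {
    truths <- rep(list(truths), length(subsamples))
  }
  stopifnot(length(truths) == length(subsamples))
  obs <- collect_stutter_observations(subsamples, truths, panel,
                                      allele_tol, caps)
  if (!"locus" %in% names(obs)) {
    obs <- tibble::tibble(locus = character(), type = character(),
                          parent_allele = double(), sr = double())
  }
  types <- names(stutter_offsets())
  entries <- purrr::map_dfr(panel$locus, function(loc) {
    purrr::map_dfr(types, function(tp) {
      o <- obs[obs$locus == loc & obs$type == tp, , drop = FALSE]
      if (nrow(o) == 0) {
        return(tibble::tibble(locus = loc, type = tp, form = "absent",
                              slope = NA_real_, intercept = NA_real_,
                              mean_sr = NA_real_, r2 = NA_real_,
                              n = 0L, sr_sd = NA_real_))
      }
      n_distinct <- length(unique(o$parent_allele))
      use_linear <- FALSE
      slope <- 0; intercept <- mean(o$sr); r2 <- 0
      if (n_distinct >= max(2, min_alleles) && nrow(o) > 2) {
        fit <- stats::lm(sr ~ parent_allele, data = o)
        sm <- summary(fit)
        pval <- stats::coef(sm)["parent_allele", "Pr(>|t|)"]
        if (is.finite(pval) && pval < p_linear) {
          use_linear <- TRUE
          slope <- unname(stats::coef(fit)[2])
          intercept <- unname(stats::coef(fit)[1])
          r2 <- sm$r.squared
        }
      }
      tibble::tibble(locus = loc, type = tp,
                     form = if (use_linear) "linear" else "mean",
                     slope = if (use_linear) slope else 0,
                     intercept = if (use_linear) intercept else 0,
                     mean_sr = mean(o$sr), r2 = r2, n = nrow(o),
                     sr_sd = stats::sd(o$sr))
    })
  })
  stutter_model(entries, caps = caps)
}

# SR observations (locus, type, parent allele, sr) from truthed
# subsamples. A stutter position is used only when it receives stutter
# from exactly one (parent allele, type) source and is not itself a true
# allele; parents sitting in a stutter position of another true allele
# are skipped (their height is composite); ratios beyond the type cap are
# discarded as non-stutter peaks (drop-in or mistyped true alleles).
collect_stutter_observations <- function(subsamples, truths, panel,
                                         allele_tol = 0.05,
                                         caps = default_stutter_caps()) {
  types <- names(stutter_offsets())
  purrr::map_dfr(seq_along(subsamples), function(i) {
    e <- subsamples[[i]]
    tr <- truths[[i]]
    purrr::map_dfr(intersect(unique(e$locus), tr$locus), function(loc) {
      pk <- e[e$locus == loc, , drop = FALSE]
      g <- unique(profile_genotype(tr, loc))
      # all stutter positions generated by the true alleles, by source
      src <- expand.grid(a = g, tp = types, stringsAsFactors = FALSE)
      src$pos <- stutter_position(src$a, src$tp)
      purrr::map_dfr(g, function(a) {
        # parent must not receive stutter from another true allele
        if (any(abs(src$pos[src$a != a] - a) <= allele_tol)) return(NULL)
        parent_h <- pk$height[abs(pk$allele - a) <= allele_tol]
        if (length(parent_h) == 0) return(NULL)
        purrr::map_dfr(types, function(tp) {
          pos <- stutter_position(a, tp)
          overlap <- abs(src$pos - pos) <= allele_tol &
            !(src$a == a & src$tp == tp)
          composite <- any(abs(g - pos) <= allele_tol) || any(overlap)
          if (composite) return(NULL)
          sh <- pk$height[abs(pk$allele - pos) <= allele_tol]
          if (length(sh) == 0) return(NULL)
          sr <- sh[1] / parent_h[1]
          if (sr > caps[[tp]]) return(NULL)
          tibble::tibble(locus = loc, type = tp, parent_allele = a,
                         sr = sr)
        })
      })
    })
  })
}

#' Estimate the drop-in rate from truth-free controls
#'
#' `rate = drop-in events / (loci scored x samples)`. An event is any
#' allelic peak surviving in a thresholded truth-free control; at most
#' `max_events_per_profile` peaks per control are counted as drop-in, and
#' controls exceeding that trigger a contamination warning. The suggested
#' drop-in cap is the smallest round thousand RFU above the maximum
#' observed drop-in height (`cap_floor` when no events).
#'
#' @param controls List of thresholded `epg` objects from zero-cell
#'   subsamples or blanks.
#' @param panel A `locus_panel`.
#' @param max_events_per_profile Contamination guard (default 2).
#' @param cap_floor Minimum suggested cap in RFU (default 1000).
#' @return A tibble with columns `rate`, `events`, `opportunities`,
#'   `cap_suggested`, `max_height`.
#' @export
estimate_drop_in_rate <- function(controls, panel = gf_panel(),
                                  max_events_per_profile = 2,
                                  cap_floor = 1000) {
  opportunities <- nrow(panel) * length(controls)
  if (opportunities == 0) stop("zero drop-in opportunities")
  events <- 0L
  max_h <- 0
  for (e in controls) {
    n_e <- nrow(e)
    if (n_e > max_events_per_profile) {
      warning("control ", epg_sample_id(e), " has ", n_e,
              " peaks; counting ", max_events_per_profile,
              " as drop-in and flagging possible contamination")
      n_e <- max_events_per_profile
    }
    events <- events + n_e
    if (nrow(e) > 0) max_h <- max(max_h, max(e$height))
  }
  cap <- if (events == 0) cap_floor else {
    max(cap_floor, 1000 * ceiling(max_h / 1000))
  }
  tibble::tibble(rate = events / opportunities, events = events,
                 opportunities = opportunities, cap_suggested = cap,
                 max_height = max_h)
}

#' Estimate the instrument saturation threshold
#'
#' Compares observed allele heights (Oa) with expected heights
#' (`Ea = back-stutter height / predicted stutter ratio`) on single-source
#' standards restricted to simple-repeat loci. Pairs are binned by Oa in
#' `bin_width`-RFU bins; the estimate is the lower edge of the first bin
#' from which the median `Oa/Ea` stays below `1 - divergence_tol` for all
#' subsequent bins. Stutter heights are unaffected by detector clipping of
#' the parent (stutter is proportional to true product), which is what
#' makes the divergence diagnostic work.
#'
#' @param standards List of thresholded `epg` objects with known
#'   single-source truths.
#' @param truths Parallel list of `ref_profile` objects (or one for all).
#' @param stutter A fitted `stutter_model` with back-stutter entries.
#' @param panel A `locus_panel`.
#' @param divergence_tol Relative divergence declaring saturation
#'   (default 0.10).
#' @param bin_width Oa bin width in RFU (default 2000).
#' @param min_pairs Minimum usable (Oa, Ea) pairs (default 50).
#' @return A tibble with `saturation_rfu` (NA when none detected) and
#'   `n_pairs`.
#' @export
estimate_saturation_threshold <- function(standards, truths, stutter,
                                          panel = gf_panel(),
                                          divergence_tol = 0.10,
                                          bin_width = 2000,
                                          min_pairs = 50) {
  if (inherits(truths, "ref_profile")) {
    truths <- rep(list(truths), length(standards))
  }
  simple <- panel$locus[panel$simple]
  pairs <- purrr::map_dfr(seq_along(standards), function(i) {
    e <- standards[[i]]
    tr <- truths[[i]]
    purrr::map_dfr(intersect(simple, unique(e$locus)), function(loc) {
      pk <- e[e$locus == loc, , drop = FALSE]
      g <- unique(profile_genotype(tr, loc))
      purrr::map_dfr(g, function(a) {
        oa <- pk$height[pk$allele == a]
        if (length(oa) == 0) return(NULL)
        pos <- stutter_position(a, "back")
        if (any(abs(g - pos) <= 0.05)) return(NULL)  # composite stutter
        sh <- pk$height[abs(pk$allele - pos) <= 0.05]
        if (length(sh) == 0) return(NULL)
        sr <- predict_sr(stutter, loc, "back", a)
        if (sr <= 0) return(NULL)
        tibble::tibble(oa = oa[1], ea = sh[1] / sr)
      })
    })
  })
  if (nrow(pairs) < min_pairs) {
    stop("insufficient (Oa, Ea) pairs for saturation estimation: ",
         nrow(pairs), " < ", min_pairs)
  }
  pairs$bin <- bin_width * floor(pairs$oa / bin_width)
  med <- pairs |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(med_ratio = stats::median(.data$oa / .data$ea),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin)
  below <- med$med_ratio < 1 - divergence_tol
  # first bin from which all subsequent bins stay below
  sat <- NA_real_
  if (any(below)) {
    tail_ok <- rev(cumprod(rev(below))) == 1
    if (any(tail_ok)) sat <- med$bin[which(tail_ok)[1]]
  }
  tibble::tibble(saturation_rfu = sat, n_pairs = nrow(pairs))
}

#' Heterozygote-balance variance bounds
#'
#' Heterozygote balance `Hb` is the ratio of the larger-size sister
#' allele's height to the smaller-size sister's; `APH` is their mean. The
#' variance scale `C^2` is the 50th percentile of the allelic peak-height
#' variance: the median of `(log10 Hb)^2 * APH`, rescaled by the median of
#' a one-degree chi-square (`qchisq(0.5, 1)`) so that it consistently
#' estimates the variance of `log10 Hb` at unit APH under a Gaussian law
#' `log10 Hb ~ N(0, C^2 / APH)`. The 95% bounds at a given APH are
#' `+/- k * sqrt(C^2 / APH)` with `k = 1.96` by default.
#'
#' @param subsamples List of thresholded `epg` objects with truths.
#' @param truths Parallel list of `ref_profile` objects (or one for all).
#' @param k Bound multiplier (default 1.96; use `2 * 1.96` for the
#'   doubled convention).
#' @param min_obs Minimum heterozygous observations (default 30).
#' @return A list of class `hb_bounds` with elements `c_squared`,
#'   `bounds` (a function of APH returning `+/-` log10 Hb bounds),
#'   `within_bounds_fraction`, `k` and `observations` (a tibble of
#'   `aph`, `log10_hb`).
#' @export
heterozygote_balance_bounds <- function(subsamples, truths, k = 1.96,
                                        min_obs = 30) {
  if (inherits(truths, "ref_profile")) {
    truths <- rep(list(truths), length(subsamples))
  }
  obs <- purrr::map_dfr(seq_along(subsamples), function(i) {
    e <- subsamples[[i]]
    tr <- truths[[i]]
    het <- tr[tr$a1 != tr$a2, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(het)), function(r) {
      pk <- e[e$locus == het$locus[r], , drop = FALSE]
      h1 <- pk$height[pk$allele == het$a1[r]]  # smaller designation/size
      h2 <- pk$height[pk$allele == het$a2[r]]  # larger
      if (length(h1) == 0 || length(h2) == 0) return(NULL)
      tibble::tibble(aph = (h1[1] + h2[1]) / 2,
                     log10_hb = log10(h2[1] / h1[1]))
    })
  })
  if (nrow(obs) == 0) stop("no heterozygous observations")
  if (nrow(obs) < min_obs) {
    stop("need at least ", min_obs, " heterozygous observations, got ",
         nrow(obs))
  }
  c2 <- stats::median(obs$log10_hb^2 * obs$aph) / stats::qchisq(0.5, 1)
  bounds <- function(aph) k * sqrt(c2 / aph)
  within <- mean(abs(obs$log10_hb) <= bounds(obs$aph))
  structure(list(c_squared = c2, bounds = bounds,
                 within_bounds_fraction = within, k = k,
                 observations = obs),
            class = "hb_bounds")
}

#' Run the full calibration pipeline on simulated or read profiles
#'
#' Convenience wrapper estimating analytical thresholds, the stutter
#' model, the drop-in rate and heterozygote-balance bounds in one call.
#'
#' @param negatives List of `noise_record` objects (for AT and drop-in).
#' @param subsamples,truths Single-source subsamples with truths (stutter
#'   and heterozygote balance).
#' @param panel A `locus_panel`.
#' @param standards,standard_truths Optional high-template standards for
#'   saturation estimation (skipped when `NULL`).
#' @param ... Passed through to [heterozygote_balance_bounds()].
#' @return A list of class `calibration_result` with elements `at`,
#'   `stutter`, `drop_in`, `saturation`, `hb`.
#' @export
calibrate <- function(negatives, subsamples, truths, panel = gf_panel(),
                      standards = NULL, standard_truths = NULL, ...) {
  at <- estimate_analytical_threshold(negatives)
  neg_epgs <- purrr::map(negatives, function(x) x$epg)
  drop_in <- estimate_drop_in_rate(neg_epgs, panel)
  stut <- fit_stutter_model(subsamples, truths, panel)
  sat <- if (!is.null(standards)) {
    estimate_saturation_threshold(standards, standard_truths, stut, panel)
  } else {
    tibble::tibble(saturation_rfu = NA_real_, n_pairs = 0L)
  }
  hb <- heterozygote_balance_bounds(subsamples, truths, ...)
  structure(list(at = at, stutter = stut, drop_in = drop_in,
                 saturation = sat, hb = hb),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat("  AT (RFU):", paste(sprintf("%s %.0f", x$at$dye, x$at$at),
                           collapse = ", "), "\n")
  cat(sprintf("  drop-in rate: %.5f (%d/%d), cap suggestion %g RFU\n",
              x$drop_in$rate, x$drop_in$events, x$drop_in$opportunities,
              x$drop_in$cap_suggested))
  cat(sprintf("  saturation: %s RFU\n",
              ifelse(is.na(x$saturation$saturation_rfu), "none detected",
                     format(x$saturation$saturation_rfu))))
  cat(sprintf("  Hb C^2: %.3f; within-bounds fraction %.3f\n",
              x$hb$c_squared, x$hb$within_bounds_fraction))
  invisible(x)
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(drop_in_rate = x$drop_in$rate,
                 drop_in_events = x$drop_in$events,
                 opportunities = x$drop_in$opportunities,
                 drop_in_cap_suggested = x$drop_in$cap_suggested,
                 saturation_rfu = x$saturation$saturation_rfu,
                 c_squared = x$hb$c_squared,
                 within_bounds_fraction = x$hb$within_bounds_fraction)
}

#' @export
tidy.stutter_model <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.stutter_model <- function(x, ...) {
  tibble::tibble(n_loci = length(unique(x$locus)),
                 n_linear = sum(x$form == "linear"),
                 n_mean = sum(x$form == "mean"),
                 n_absent = sum(x$form == "absent"),
                 mean_r2 = mean(x$r2[x$form == "linear"]))
}
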