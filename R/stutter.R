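#' Stutter types and repeat offsets
#'
#' Six PCR stutter artifact types are modeled, identified by their offset
#' from the parent allele in repeat units: back (-1), forward (+1),
#' double_back (-2), half_back (-0.5), half_forward (+0.5) and minus_1p5
#' (-1.5 repeats).
#'
#' @return A named numeric vector of allele-number offsets.
#' @export
stutter_offsets <- function() {
  c(back = -1, forward = 1, double_back = -2,
    half_back = -0.5, half_forward = 0.5, minus_1p5 = -1.5)
}

#' Default maximum stutter-ratio caps per type
#'
#' Elevated caps appropriate for low-template single-cell subsamples:
#' back 0.7, forward 0.7, double-back 0.3, half-back 0.5, half-forward
#' 0.15, -1.5 repeat 0.15. Predicted stutter ratios are truncated to
#' `[0, cap]`.
#'
#' @return A named numeric vector of caps.
#' @export
default_stutter_caps <- function() {
  c(back = 0.7, forward = 0.7, double_back = 0.3,
    half_back = 0.5, half_forward = 0.15, minus_1p5 = 0.15)
}

#' Construct a stutter model
#'
#' A stutter model holds, per locus and stutter type, either a linear
#' stutter-ratio (SR) regression on parent allele number
#' (`form = "linear"`, slope and intercept) or a mean SR
#' (`form = "mean"`), together with the per-type maximum-SR cap and fit
#' diagnostics. Entries with `form = "absent"` fall back to the panel-wide
#' mean SR of the type at prediction time.
#'
#' @param entries A data frame with columns `locus`, `type`, `form`
#'   (`"linear"`, `"mean"` or `"absent"`), `slope`, `intercept`, `mean_sr`,
#'   and optionally `r2`, `n`, `sr_sd`.
#' @param caps Named numeric vector of per-type maximum-SR caps; defaults
#'   to [default_stutter_caps()].
#' @return A tibble of class `stutter_model`.
#' @export
stutter_model <- function(entries, caps = default_stutter_caps()) {
  e <- tibble::as_tibble(entries)
  needed <- c("locus", "type", "form", "slope", "intercept", "mean_sr")
  missing <- setdiff(needed, names(e))
  if (length(missing) > 0) {
    stop("stutter model missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(e$type), names(stutter_offsets()))
  if (length(bad) > 0) {
    stop("unknown stutter type(s): ", paste(bad, collapse = ", "))
  }
  if (!"r2" %in% names(e)) e$r2 <- NA_real_
  if (!"n" %in% names(e)) e$n <- NA_integer_
  if (!"sr_sd" %in% names(e)) e$sr_sd <- NA_real_
  if (!"cap" %in% names(e)) e$cap <- unname(caps[e$type])
  structure(e, caps = caps,
            class = c("stutter_model", class(tibble::tibble())))
}

#' Predict a stutter ratio
#'
#' Evaluates the fitted per-locus model for a stutter type at the given
#' parent allele number(s) and truncates to `[0, cap]`. Loci without a
#' usable fit fall back to the mean SR of that type across loci (0 when no
#' locus has one).
#'
#' @param model A `stutter_model`.
#' @param locus Locus name (scalar).
#' @param type Stutter type name.
#' @param allele Parent allele number(s).
#' @return Predicted stutter ratio(s) in `[0, cap]`.
#' @export
predict_sr <- function(model, locus, type, allele) {
  if (!type %in% names(stutter_offsets())) {
    stop("unknown stutter type: ", type)
  }
  cap <- unname(attr(model, "caps")[type])
  row <- model[model$locus == locus & model$type == type, , drop = FALSE]
  if (nrow(row) == 0 || row$form[1] == "absent") {
    # fall back to the panel-wide mean SR of the type (mean_sr is
    # recorded for linear entries too)
    rows_t <- model[model$type == type & model$form != "absent", ,
                    drop = FALSE]
    fallback <- if (nrow(rows_t) == 0) 0 else mean(rows_t$mean_sr)
    if (is.na(fallback)) fallback <- 0
    return(pmin(pmax(rep(fallback, length(allele)), 0), cap))
  }
  sr <- if (row$form[1] == "linear") {
    row$slope[1] * allele + row$intercept[1]
  } else {
    rep(row$mean_sr[1], length(allele))
  }
  pmin(pmax(sr, 0), cap)
}

#' Default stutter model for simulation
#'
#' A study-condition stutter model for the default panel: back stutter is
#' linear in allele number (for D16S539 the regression line
#' `SR = 0.0177 * allele - 0.1249`; other loci use the same slope with the
#' intercept anchored so SR is about 0.085 at the locus's central allele),
#' the remaining five types use mean SRs typical of elevated low-template
#' stutter. `sr_sd` is the per-type Gaussian noise of simulated SRs.
#'
#' @param panel A `locus_panel`.
#' @param sr_sd Named numeric vector of per-type SR noise standard
#'   deviations used by the simulator.
#' @return A `stutter_model`.
#' @export
default_stutter_model <- function(panel = gf_panel(),
                                  sr_sd = c(back = 0.03, forward = 0.015,
                                            double_back = 0.01,
                                            half_back = 0.015,
                                            half_forward = 0.008,
                                            minus_1p5 = 0.008)) {
  type_means <- c(forward = 0.035, double_back = 0.02, half_back = 0.05,
                  half_forward = 0.012, minus_1p5 = 0.012)
  slope <- 0.0177
  rows <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    loc <- panel$locus[i]
    centre <- (panel$allele_min[i] + panel$allele_max[i]) / 2
    intercept <- if (loc == "D16S539") -0.1249 else 0.085 - slope * centre
    back <- tibble::tibble(locus = loc, type = "back", form = "linear",
                           slope = slope, intercept = intercept,
                           mean_sr = slope * centre + intercept)
    others <- tibble::tibble(locus = loc, type = names(type_means),
                             form = "mean", slope = 0, intercept = 0,
                             mean_sr = unname(type_means))
    dplyr::bind_rows(back, others)
  })
  rows$sr_sd <- unname(sr_sd[rows$type])
  stutter_model(rows)
}

# allele positions at which a stutter of `type` from `parent` would appear
stutter_position <- function(parent, type) {
  unname(parent + stutter_offsets()[type])
}

#' Remove unmodeled stutter peaks from an EPG
#'
#' Removes any peak that sits at a stutter position (of one of the named
#' types) relative to a larger same-locus parent peak, provided its height
#' ratio to that parent does not exceed the type's maximum-SR cap. Peaks
#' exceeding the cap are retained as true-allele candidates, as are parent
#' peaks. Used to strip stutter types a downstream model does not handle
#' (e.g. half-back and double-back stutter ahead of an engine that models
#' only back and forward stutter).
#'
#' @param x A thresholded `epg`.
#' @param stutter A `stutter_model` (supplies the caps).
#' @param types_to_remove Character vector of stutter type names; empty
#'   means no-op.
#' @param allele_tol Tolerance, in repeat units, for matching stutter
#'   positions (default 0.05).
#' @return A filtered `epg`.
#' @export
filter_unmodeled_stutter <- function(x, stutter,
                                     types_to_remove = c("half_back",
                                                         "double_back"),
                                     allele_tol = 0.05) {
  bad <- setdiff(types_to_remove, names(stutter_offsets()))
  if (length(bad) > 0) {
    stop("unknown stutter type(s): ", paste(bad, collapse = ", "))
  }
  if (length(types_to_remove) == 0 || nrow(x) == 0) return(x)
  caps <- attr(stutter, "caps")
  drop <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(x))) {
    same <- which(x$locus == x$locus[i] & x$height > x$height[i])
    for (j in same) {
      for (tp in types_to_remove) {
        pos <- stutter_position(x$allele[j], tp)
        if (abs(x$allele[i] - pos) <= allele_tol &&
            x$height[i] / x$height[j] <= caps[[tp]]) {
          drop[i] <- TRUE
        }
      }
    }
  }
  epg_replace_peaks(x, tibble::as_tibble(x)[!drop, , drop = FALSE])
}
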