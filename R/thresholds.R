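#' Per-dye analytical thresholds
#'
#' The analytical threshold (AT) is the minimum peak height, in RFU, scored
#' per dye channel. Defaults are the DSCS values determined from negative
#' controls: Blue 53, Green 86, Yellow 46, Red 63, Purple 63.
#'
#' @param Blue,Green,Yellow,Red,Purple Positive RFU thresholds.
#' @return A tibble of class `at_thresholds` with columns `dye`, `at`.
#' @export
at_thresholds <- function(Blue = 53, Green = 86, Yellow = 46,
                          Red = 63, Purple = 63) {
  at <- c(Blue = Blue, Green = Green, Yellow = Yellow, Red = Red,
          Purple = Purple)
  if (any(!is.finite(at)) || any(at <= 0)) {
    stop("analytical thresholds must be positive")
  }
  structure(tibble::tibble(dye = names(at), at = unname(at)),
            class = c("at_thresholds", class(tibble::tibble())))
}

# named lookup vector from an at_thresholds tibble (or passthrough)
at_vector <- function(at) {
  if (inherits(at, "at_thresholds") || is.data.frame(at)) {
    stats::setNames(at$at, at$dye)
  } else if (is.numeric(at) && !is.null(names(at))) {
    at
  } else {
    stop("`at` must be an at_thresholds table or a named numeric vector")
  }
}

#' Apply the analytical threshold to an EPG
#'
#' Removes every peak whose height is below its dye-channel threshold.
#' Peaks exactly at the threshold are retained (`>=` comparison). The input
#' is not modified; a new EPG flagged `at_applied` is returned.
#'
#' @param x An `epg`.
#' @param at An `at_thresholds` table (or named numeric vector by dye).
#' @param panel A `locus_panel` giving each locus's dye.
#' @return A thresholded `epg`.
#' @export
apply_analytical_threshold <- function(x, at, panel) {
  atv <- at_vector(at)
  if (nrow(x) == 0) return(epg_replace_peaks(x, x, at_applied = TRUE))
  dyes <- locus_dye(panel, x$locus)
  missing <- setdiff(unique(dyes), names(atv))
  if (length(missing) > 0) {
    stop("no analytical threshold for dye(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- x$height >= atv[dyes]
  epg_replace_peaks(x, tibble::as_tibble(x)[keep, , drop = FALSE],
                    at_applied = TRUE)
}
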