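#' Plot fitted stutter-ratio regressions
#'
#' One line (or level) per locus for a given stutter type, over each
#' locus's allele range, with the type's maximum-SR cap drawn as a dashed
#' line.
#'
#' @param object A `stutter_model`.
#' @param type Stutter type to display (default `"back"`).
#' @param panel A `locus_panel` providing allele ranges.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stutter_model <- function(object, type = "back",
                                   panel = gf_panel(), ...) {
  dat <- purrr::map_dfr(panel$locus, function(loc) {
    al <- seq(panel$allele_min[panel$locus == loc],
              panel$allele_max[panel$locus == loc], by = 0.5)
    tibble::tibble(locus = loc, allele = al,
                   sr = predict_sr(object, loc, type, al))
  })
  cap <- attr(object, "caps")[[type]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$allele, y = .data$sr,
                                    colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cap, linetype = "dashed") +
    ggplot2::labs(x = "parent allele number", y = "stutter ratio",
                  title = paste(type, "stutter")) +
    ggplot2::theme_minimal()
}

#' Plot heterozygote balance against average peak height
#'
#' The classic log10(Hb) vs APH scatter with the fitted
#' `+/- k * sqrt(C^2 / APH)` variance bounds.
#'
#' @param x An `hb_bounds` result from [heterozygote_balance_bounds()].
#' @return A ggplot object.
#' @export
plot_hb_bounds <- function(x) {
  obs <- x$observations
  grid <- tibble::tibble(aph = seq(min(obs$aph), max(obs$aph),
                                   length.out = 200))
  grid$upper <- x$bounds(grid$aph)
  grid$lower <- -grid$upper
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$aph, y = .data$log10_hb)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$upper), colour = "red",
                       linetype = "dashed") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$lower), colour = "red",
                       linetype = "dashed") +
    ggplot2::labs(x = "average peak height (RFU)",
                  y = "log10 heterozygote balance") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' Chooses a display suited to the design: log10 LR versus detected
#' allele count for sensitivity/specificity runs (LR = 0 rendered at a
#' sentinel), a paired scatter with the y = x line for NOC
#' misspecification, and grouped per-donor bars
#' (Reference / STD Mix / DSCS Replicate) for mixture deconvolution.
#'
#' @param object An `experiment_report`.
#' @param sentinel Rendering value for LR = 0 (default -50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, sentinel = -50, ...) {
  r <- object$records
  if (object$design == "noc_misspecification") {
    dat <- dplyr::mutate(r,
                         x = render_log10_lr(.data$lr_true_noc, sentinel),
                         y = render_log10_lr(.data$lr_alt_noc, sentinel))
    return(ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$class)) +
             ggplot2::geom_point() +
             ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed") +
             ggplot2::labs(x = "log10 LR at true NOC",
                           y = "log10 LR at misspecified NOC") +
             ggplot2::theme_minimal())
  }
  if (object$design == "mixture_deconvolution") {
    dat <- r |>
      tidyr::pivot_longer(cols = c("reference_log10",
                                   "dscs_replicate_log10",
                                   "std_mix_log10"),
                          names_to = "method", values_to = "log10_lr") |>
      dplyr::mutate(method = dplyr::recode(.data$method,
                                           reference_log10 = "Reference",
                                           dscs_replicate_log10 =
                                             "DSCS Replicate",
                                           std_mix_log10 = "STD Mix"))
    return(ggplot2::ggplot(dat,
                           ggplot2::aes(x = .data$donor,
                                        y = .data$log10_lr,
                                        fill = .data$method)) +
             ggplot2::geom_col(position = "dodge") +
             ggplot2::facet_wrap(~mixture_noc, scales = "free_x") +
             ggplot2::labs(x = "donor", y = "log10 LR") +
             ggplot2::theme_minimal() +
             ggplot2::theme(axis.text.x =
                              ggplot2::element_text(angle = 45,
                                                    hjust = 1)))
  }
  dat <- dplyr::mutate(r, shown = render_log10_lr(.data$log10_lr,
                                                  sentinel))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_alleles,
                                    y = .data$shown,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(0, 6), linetype = "dashed") +
    ggplot2::labs(x = "alleles detected", y = "log10 LR") +
    ggplot2::theme_minimal()
}
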