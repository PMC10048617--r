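#' Write and read a run configuration
#'
#' Serialises a [sim_config()] to YAML, embedding the stutter model as a
#' plain table, so a simulation's full configuration round-trips through
#' a text file alongside its outputs.
#'
#' @param cfg A `sim_config`.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$at <- as.list(stats::setNames(cfg$at$at, cfg$at$dye))
  if (!is.null(cfg$stutter)) {
    x$stutter <- lapply(seq_len(nrow(cfg$stutter)), function(i) {
      as.list(tibble::as_tibble(cfg$stutter)[i, ])
    })
    x$stutter_caps <- as.list(attr(cfg$stutter, "caps"))
  }
  if (!is.null(cfg$inhibition)) x$inhibition <- as.list(cfg$inhibition)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  at <- do.call(at_thresholds, x$at)
  stutter <- if (!is.null(x$stutter)) {
    stutter_model(dplyr::bind_rows(lapply(x$stutter, tibble::as_tibble)),
                  caps = unlist(x$stutter_caps))
  } else NULL
  inhibition <- if (!is.null(x$inhibition)) unlist(x$inhibition) else NULL
  sim_config(mean_height_per_cell = x$mean_height_per_cell,
             cv_peak = x$cv_peak, lsae_sd = x$lsae_sd,
             stutter = stutter, drop_in_rate = x$drop_in_rate,
             drop_in_lambda = x$drop_in_lambda,
             drop_in_unif = x$drop_in_unif,
             drop_in_cap = x$drop_in_cap, degradation = x$degradation,
             size_ref = x$size_ref, inhibition = inhibition,
             saturation = x$saturation, at = at,
             baseline_sd = x$baseline_sd,
             baseline_points = x$baseline_points,
             cycles_note = x$cycles_note)
}
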