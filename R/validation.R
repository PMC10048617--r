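#' Experiment report container
#'
#' All validation experiments return an `experiment_report`: the design
#' name, the per-sample record table (each record carries the seed that
#' generated it), aggregate rates recomputed from the records at build
#' time, the experiment seed and a config snapshot.
#'
#' @param design Design name.
#' @param records Per-sample tibble; must contain `log10_lr` and the
#'   threshold flags `above_0`, `above_6` where applicable.
#' @param aggregates Aggregate tibble (recomputable from `records`).
#' @param seed Experiment seed.
#' @param config Config snapshot (list).
#' @return A list of class `experiment_report`.
#' @export
experiment_report <- function(design, records, aggregates, seed, config) {
  structure(list(design = design, records = records,
                 aggregates = aggregates, seed = seed, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (%d records, seed %s)\n",
              x$design, nrow(x$records), x$seed))
  print(x$aggregates)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$records

#' @export
glance.experiment_report <- function(x, ...) x$aggregates

#' Write an experiment report as delimited text
#'
#' Writes `<stem>_records.csv`, `<stem>_aggregates.csv` and a
#' `<stem>_manifest.csv` run manifest (design, seed, package version and
#' scalar config entries). Aggregates are recomputed from the records at
#' write time and must agree with the stored aggregates.
#'
#' @param x An `experiment_report`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_experiment_report <- function(x, stem) {
  agg2 <- recompute_aggregates(x)
  if (!is.null(agg2) && !isTRUE(all.equal(
    as.data.frame(agg2), as.data.frame(x$aggregates),
    tolerance = 1e-8))) {
    stop("stored aggregates disagree with the per-sample records")
  }
  readr::write_csv(x$records, paste0(stem, "_records.csv"))
  readr::write_csv(x$aggregates, paste0(stem, "_aggregates.csv"))
  scalars <- x$config[vapply(x$config, function(v) {
    is.atomic(v) && length(v) == 1
  }, TRUE)]
  manifest <- tibble::tibble(
    key = c("design", "seed", "package_version", names(scalars)),
    value = c(x$design, as.character(x$seed),
              as.character(utils::packageVersion("strpg")),
              vapply(scalars, as.character, "")))
  readr::write_csv(manifest, paste0(stem, "_manifest.csv"))
  invisible(stem)
}

# recompute the threshold-rate aggregates from records (where possible)
recompute_aggregates <- function(x) {
  r <- x$records
  if (!all(c("class", "above_0", "above_6") %in% names(r))) return(NULL)
  r |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     pct_above_0 = 100 * mean(.data$above_0),
                     pct_above_6 = 100 * mean(.data$above_6),
                     .groups = "drop")
}

# strip all modeled stutter types ahead of the semi-continuous engine
# (which has no stutter model of its own)
strip_stutter <- function(e, cfg) {
  if (is.null(cfg$stutter)) return(e)
  filter_unmodeled_stutter(e, cfg$stutter, names(stutter_offsets()))
}

# simulate one subsample for a donor set and compute the true-donor LR
sc_lr_for <- function(reps, donor, n_unknowns_hp, noc_hd, freqs, panel,
                      dropin_rate, loci = NULL) {
  th <- freq_theta(freqs)
  hp <- hypothesis(donor, n_unknowns = n_unknowns_hp, theta = th)
  hd <- hypothesis(list(), noc_hd, theta = th)
  # fractional stutter positions surviving the filter routinely trigger
  # the minimum-frequency policy; that is expected here
  suppressWarnings(
    semicontinuous_replicate_lr(reps, hp, hd, freqs, panel,
                                dropin_rate = dropin_rate, loci = loci))
}

#' Sensitivity/specificity experiment
#'
#' Simulates three subsample classes (1-cell single source, 2-cell single
#' source, 2-cell mini-mixtures), computes true-donor LRs per subsample,
#' groups same-donor subsamples into replicate groups of 3-5 (members
#' screened at log10 LR > 1) and computes joint replicate LRs, and
#' optionally searches a known non-contributor database for false
#' positives. Inclusion is tabulated at the log10(LR) thresholds 0 and 6.
#'
#' @param freqs An `allele_freqs` table.
#' @param cfg A [sim_config()].
#' @param panel A `locus_panel`.
#' @param n_1cell,n_2cell_ss,n_2cell_mix Class sizes (defaults 110, 81,
#'   50).
#' @param n_donors Donor pool size.
#' @param db_size Non-contributor database size (0 skips the search).
#' @param db_subsample_idx Indices of subsamples searched against the
#'   database (defaults to all when a database is used).
#' @param seed Experiment seed.
#' @param thresholds Log10 LR thresholds (fixed named constants 0 and 6,
#'   overridable).
#' @return An `experiment_report`; records have classes
#'   `ss_1cell`, `ss_2cell`, `mix_2cell`, `replicate`, and
#'   `non_contributor` when a database is searched.
#' @export
sensitivity_specificity_experiment <- function(freqs, cfg = sim_config(),
                                               panel = gf_panel(),
                                               n_1cell = 110,
                                               n_2cell_ss = 81,
                                               n_2cell_mix = 50,
                                               n_donors = 8,
                                               db_size = 0,
                                               db_subsample_idx = NULL,
                                               seed = 1,
                                               thresholds = c(0, 6)) {
  stopifnot(n_1cell >= 1, n_2cell_ss >= 1, n_2cell_mix >= 1)
  seeds <- derive_seeds(seed, 6)
  donors <- sample_reference_profiles(freqs, n_donors, seed = seeds[1],
                                      prefix = "K")
  th <- freq_theta(freqs)

  plan <- dplyr::bind_rows(
    tibble::tibble(class = "ss_1cell", idx = seq_len(n_1cell), cells = 1L),
    tibble::tibble(class = "ss_2cell", idx = seq_len(n_2cell_ss),
                   cells = 2L),
    tibble::tibble(class = "mix_2cell", idx = seq_len(n_2cell_mix),
                   cells = 2L))
  sub_seeds <- derive_seeds(seeds[2], nrow(plan))
  set.seed(seeds[3])
  plan$donor1 <- sample.int(n_donors, nrow(plan), replace = TRUE)
  plan$donor2 <- vapply(plan$donor1, function(d1) {
    sample(setdiff(seq_len(n_donors), d1), 1)
  }, 0L)

  sims <- vector("list", nrow(plan))
  rec <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cls <- plan$class[i]
    d1 <- donors[[plan$donor1[i]]]
    if (cls == "mix_2cell") {
      d2 <- donors[[plan$donor2[i]]]
      e <- simulate_subsample(list(list(profile = d1, cells = 1L),
                                   list(profile = d2, cells = 1L)),
                              cfg, panel, seed = sub_seeds[i],
                              sample_id = sprintf("%s-%03d", cls,
                                                  plan$idx[i]))
      e <- strip_stutter(e, cfg)
      res <- sc_lr_for(list(e), d1, 1, 2, freqs, panel, cfg$drop_in_rate)
    } else {
      e <- simulate_subsample(list(list(profile = d1,
                                        cells = plan$cells[i])),
                              cfg, panel, seed = sub_seeds[i],
                              sample_id = sprintf("%s-%03d", cls,
                                                  plan$idx[i]))
      e <- strip_stutter(e, cfg)
      res <- sc_lr_for(list(e), d1, 0, 1, freqs, panel, cfg$drop_in_rate)
    }
    sims[[i]] <- e
    rec[[i]] <- tibble::tibble(
      sample_id = epg_sample_id(e), class = cls,
      truth = profile_donor_id(d1), model = "semi_continuous",
      noc = if (cls == "mix_2cell") 2L else 1L,
      n_alleles = epg_allele_count(e),
      log10_lr = res$log10_lr_total, seed = sub_seeds[i])
  }
  records <- dplyr::bind_rows(rec)

  # replicate groups per donor per class
  group_rec <- list()
  set.seed(seeds[4])
  for (cls in unique(plan$class)) {
    for (dn in seq_len(n_donors)) {
      members <- which(plan$class == cls & plan$donor1 == dn)
      while (length(members) >= 3) {
        size <- min(sample(3:5, 1), length(members))
        take <- members[seq_len(size)]
        members <- members[-seq_len(size)]
        pass <- take[records$log10_lr[take] > 1]
        use <- if (length(pass) >= 2) pass else {
          take[which.max(records$log10_lr[take])]
        }
        res <- sc_lr_for(sims[use], donors[[dn]],
                         if (cls == "mix_2cell") 1 else 0,
                         if (cls == "mix_2cell") 2 else 1,
                         freqs, panel, cfg$drop_in_rate)
        group_rec[[length(group_rec) + 1L]] <- tibble::tibble(
          sample_id = sprintf("rep-%s-%s-%d", cls,
                              profile_donor_id(donors[[dn]]),
                              length(group_rec) + 1L),
          class = "replicate", truth = profile_donor_id(donors[[dn]]),
          model = "semi_continuous",
          noc = if (cls == "mix_2cell") 2L else 1L,
          n_alleles = NA_integer_,
          log10_lr = res$log10_lr_total, seed = seeds[4],
          members = paste(records$sample_id[take], collapse = ";"))
      }
    }
  }
  records <- dplyr::bind_rows(records, dplyr::bind_rows(group_rec))

  # non-contributor database search
  if (db_size > 0) {
    db <- sample_reference_profiles(freqs, db_size, seed = seeds[5],
                                    prefix = "NC")
    if (is.null(db_subsample_idx)) db_subsample_idx <- seq_along(sims)
    nc <- purrr::map_dfr(db_subsample_idx, function(i) {
      hits <- database_search(list(sims[[i]]), db, freqs, panel,
                              model = "semi_continuous",
                              hd_unknowns = if (plan$class[i] ==
                                                "mix_2cell") 2 else 1,
                              dropin_rate = cfg$drop_in_rate)
      tibble::tibble(sample_id = epg_sample_id(sims[[i]]),
                     class = "non_contributor",
                     truth = hits$donor_id, model = "semi_continuous",
                     noc = if (plan$class[i] == "mix_2cell") 2L else 1L,
                     n_alleles = NA_integer_, log10_lr = hits$log10_lr,
                     seed = seeds[5])
    })
    records <- dplyr::bind_rows(records, nc)
  }

  records$above_0 <- is.finite(records$log10_lr) &
    records$log10_lr > thresholds[1]
  records$above_6 <- is.finite(records$log10_lr) &
    records$log10_lr >= thresholds[2]
  agg <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     pct_above_0 = 100 * mean(.data$above_0),
                     pct_above_6 = 100 * mean(.data$above_6),
                     .groups = "drop")
  experiment_report("sensitivity_specificity", records, agg, seed,
                    list(n_1cell = n_1cell, n_2cell_ss = n_2cell_ss,
                         n_2cell_mix = n_2cell_mix, db_size = db_size,
                         drop_in_rate = cfg$drop_in_rate, theta = th))
}

#' Number-of-contributors misspecification experiment
#'
#' Single-source subsamples are evaluated at the true NOC (N = 1) and
#' overestimated (N = 2); two-person mini-mixtures at N = 2 and
#' underestimated (N = 1). Reports paired log10 LRs, sign changes, and
#' zero-LR cases rescued by N + 1.
#'
#' @inheritParams sensitivity_specificity_experiment
#' @param n_single_source,n_minimix Numbers of subsamples (default 35).
#' @return An `experiment_report` with one record per subsample/NOC pair.
#' @export
noc_misspecification_experiment <- function(freqs, cfg = sim_config(),
                                            panel = gf_panel(),
                                            n_single_source = 35,
                                            n_minimix = 35,
                                            n_donors = 8, seed = 1) {
  seeds <- derive_seeds(seed, 3)
  donors <- sample_reference_profiles(freqs, n_donors, seed = seeds[1],
                                      prefix = "K")
  sub_seeds <- derive_seeds(seeds[2], n_single_source + n_minimix)
  set.seed(seeds[3])
  rec <- list()
  for (i in seq_len(n_single_source)) {
    dn <- sample.int(n_donors, 1)
    e <- simulate_subsample(list(list(profile = donors[[dn]],
                                      cells = sample(1:2, 1))),
                            cfg, panel, seed = sub_seeds[i],
                            sample_id = sprintf("ss-%03d", i))
    e <- strip_stutter(e, cfg)
    r1 <- sc_lr_for(list(e), donors[[dn]], 0, 1, freqs, panel,
                    cfg$drop_in_rate)
    r2 <- sc_lr_for(list(e), donors[[dn]], 1, 2, freqs, panel,
                    cfg$drop_in_rate)
    rec[[length(rec) + 1L]] <- tibble::tibble(
      sample_id = epg_sample_id(e), class = "single_source",
      truth = profile_donor_id(donors[[dn]]),
      lr_true_noc = r1$log10_lr_total, lr_alt_noc = r2$log10_lr_total,
      true_noc = 1L, alt_noc = 2L, seed = sub_seeds[i])
  }
  for (i in seq_len(n_minimix)) {
    dns <- sample.int(n_donors, 2)
    e <- simulate_subsample(list(list(profile = donors[[dns[1]]],
                                      cells = 1L),
                                 list(profile = donors[[dns[2]]],
                                      cells = 1L)),
                            cfg, panel,
                            seed = sub_seeds[n_single_source + i],
                            sample_id = sprintf("mix-%03d", i))
    e <- strip_stutter(e, cfg)
    r2 <- sc_lr_for(list(e), donors[[dns[1]]], 1, 2, freqs, panel,
                    cfg$drop_in_rate)
    r1 <- sc_lr_for(list(e), donors[[dns[1]]], 0, 1, freqs, panel,
                    cfg$drop_in_rate)
    rec[[length(rec) + 1L]] <- tibble::tibble(
      sample_id = epg_sample_id(e), class = "mini_mixture",
      truth = profile_donor_id(donors[[dns[1]]]),
      lr_true_noc = r2$log10_lr_total, lr_alt_noc = r1$log10_lr_total,
      true_noc = 2L, alt_noc = 1L, seed = sub_seeds[n_single_source + i])
  }
  records <- dplyr::bind_rows(rec)
  agg <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_sign_change = sum(sign(pmax(.data$lr_true_noc, -999)) !=
                            sign(pmax(.data$lr_alt_noc, -999))),
      n_zero_rescued = sum(!is.finite(.data$lr_true_noc) &
                             is.finite(.data$lr_alt_noc) &
                             .data$lr_alt_noc > 0),
      n_excluded_at_alt = sum(!(.data$lr_alt_noc > 0) |
                                !is.finite(.data$lr_alt_noc)),
      .groups = "drop")
  experiment_report("noc_misspecification", records, agg, seed,
                    list(n_single_source = n_single_source,
                         n_minimix = n_minimix,
                         drop_in_rate = cfg$drop_in_rate))
}

#' Replicate misclassification experiment
#'
#' Computes a replicate LR from correct-donor subsamples, then repeats the
#' analysis with each intruder (a wrong-donor subsample) added to the
#' replicate set, reporting the change in the true-donor log10 LR. Engine
#' model failures are recorded as a distinct outcome (`"FAIL"`), never as
#' LR = 0.
#'
#' @inheritParams sensitivity_specificity_experiment
#' @param group_epgs List of correct-donor `epg` replicates.
#' @param donor The true donor's `ref_profile`.
#' @param intruders Named list of wrong-donor `epg` objects.
#' @param engine `"semi_continuous"` or `"quantitative"`.
#' @param noc Contributors assumed (1 for single-source groups).
#' @return An `experiment_report`; records hold the baseline and
#'   with-intruder replicate LRs and intruder allele counts.
#' @export
replicate_misclassification_experiment <- function(group_epgs, donor,
                                                   intruders, freqs,
                                                   cfg = sim_config(),
                                                   panel = gf_panel(),
                                                   engine = "semi_continuous",
                                                   noc = 1, seed = 1) {
  th <- freq_theta(freqs)
  hp <- hypothesis(donor, n_unknowns = noc - 1, theta = th)
  hd <- hypothesis(list(), noc, theta = th)
  run <- function(reps) {
    res <- tryCatch({
      if (engine == "semi_continuous") {
        semicontinuous_replicate_lr(reps, hp, hd, freqs, panel,
                                    dropin_rate = cfg$drop_in_rate)
      } else {
        quantitative_replicate_lr(reps, hp, hd, freqs, panel,
                                  at = cfg$at, seed = seed)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      list(lr = NA_real_, status = "FAIL")
    } else {
      list(lr = res$log10_lr_total, status = res$status)
    }
  }
  base <- run(group_epgs)
  rec <- purrr::map_dfr(seq_along(intruders), function(i) {
    with_i <- run(c(group_epgs, intruders[i]))
    nm <- names(intruders)[i]
    tibble::tibble(
      sample_id = if (is.null(nm) || nm == "") sprintf("intruder-%d", i)
                  else nm,
      class = "misclassified",
      truth = profile_donor_id(donor),
      intruder_alleles = epg_allele_count(intruders[[i]]),
      lr_baseline = base$lr, lr_with_intruder = with_i$lr,
      delta = with_i$lr - base$lr,
      status = with_i$status, seed = seed)
  })
  agg <- tibble::tibble(
    n = nrow(rec),
    baseline_log10_lr = base$lr,
    baseline_status = base$status,
    n_fail = sum(rec$status == "FAIL"),
    n_excluding = sum(rec$status == "ok" &
                        (!is.finite(rec$lr_with_intruder) |
                           rec$lr_with_intruder <= 0)))
  experiment_report("replicate_misclassification", rec, agg, seed,
                    list(engine = engine, noc = noc,
                         n_group = length(group_epgs)))
}

#' Mixture deconvolution experiment
#'
#' For equimolar mixtures of 2-6 donors, compares three per-donor
#' quantities: the reference ceiling `log10(1/RMP)` from the donor's
#' profile, the DSCS replicate log10 LR from simulated single-donor
#' subsample groups, and the bulk standard-analysis LR (computed only
#' where the contributor count is within engine reach; 5- and 6-person
#' bulk analysis is refused, mirroring the reference software's
#' four-person recommendation).
#'
#' @inheritParams sensitivity_specificity_experiment
#' @param noc_list Mixture sizes (default `2:6`).
#' @param group_size Subsamples per DSCS replicate group (default 4).
#' @param group_cells Cells per subsample (default 2).
#' @param bulk_cells_per_donor Cells per donor in the bulk mixture
#'   (default 10).
#' @param max_bulk_noc Largest NOC attempted in bulk standard analysis
#'   (default 3, the semi-continuous enumeration limit; 4 is the
#'   reference software's recommended cap, 5-6 always refused).
#' @return An `experiment_report` with one record per mixture and donor.
#' @export
mixture_deconvolution_experiment <- function(freqs, cfg = sim_config(),
                                             panel = gf_panel(),
                                             noc_list = 2:6,
                                             group_size = 4,
                                             group_cells = 2,
                                             bulk_cells_per_donor = 10,
                                             max_bulk_noc = 3,
                                             seed = 1) {
  th <- freq_theta(freqs)
  seeds <- derive_seeds(seed, length(noc_list) + 1)
  rec <- list()
  for (mi in seq_along(noc_list)) {
    noc <- noc_list[mi]
    mseeds <- derive_seeds(seeds[mi], 2 + noc * (group_size + 1))
    donors <- sample_reference_profiles(freqs, noc, seed = mseeds[1],
                                        prefix = sprintf("M%d_", noc))
    bulk <- simulate_subsample(
      lapply(donors, function(d) list(profile = d,
                                      cells = bulk_cells_per_donor)),
      cfg, panel, seed = mseeds[2],
      sample_id = sprintf("bulk-%dp", noc))
    bulk <- strip_stutter(bulk, cfg)
    si <- 2
    for (k in seq_len(noc)) {
      ref_lr <- single_source_profile_lr(donors[[k]], freqs)
      reps <- lapply(seq_len(group_size), function(j) {
        si <<- si + 1
        simulate_subsample(list(list(profile = donors[[k]],
                                     cells = group_cells)),
                           cfg, panel, seed = mseeds[si],
                           sample_id = sprintf("dscs-%dp-%d-%d",
                                               noc, k, j))
      })
      reps <- lapply(reps, strip_stutter, cfg = cfg)
      # screen members at log10 LR > 1 before joint replicate analysis
      ind <- vapply(reps, function(e) {
        sc_lr_for(list(e), donors[[k]], 0, 1, freqs, panel,
                  cfg$drop_in_rate)$log10_lr_total
      }, 0)
      use <- if (any(ind > 1)) reps[ind > 1] else {
        reps[which.max(ind)]
      }
      dscs <- sc_lr_for(use, donors[[k]], 0, 1, freqs, panel,
                        cfg$drop_in_rate)
      if (noc > 4) {
        std_lr <- NA_real_
        std_status <- "not supported: bulk probabilistic genotyping is only recommended on mixtures of up to four people"
      } else if (noc > max_bulk_noc) {
        std_lr <- NA_real_
        std_status <- sprintf(
          "engine limit: exact enumeration caps at %d contributors",
          max_bulk_noc)
      } else {
        std <- sc_lr_for(list(bulk), donors[[k]], noc - 1, noc, freqs,
                         panel, cfg$drop_in_rate)
        std_lr <- std$log10_lr_total
        std_status <- "ok"
      }
      rec[[length(rec) + 1L]] <- tibble::tibble(
        mixture_noc = noc, donor = profile_donor_id(donors[[k]]),
        reference_log10 = ref_lr$log10_lr_total,
        dscs_replicate_log10 = dscs$log10_lr_total,
        std_mix_log10 = std_lr, std_status = std_status,
        n_replicates_used = length(use), seed = mseeds[1])
    }
  }
  records <- dplyr::bind_rows(rec)
  agg <- records |>
    dplyr::group_by(.data$mixture_noc) |>
    dplyr::summarise(
      n_donors = dplyr::n(),
      mean_reference = mean(.data$reference_log10),
      mean_dscs = mean(.data$dscs_replicate_log10),
      n_dscs_positive = sum(.data$dscs_replicate_log10 > 0),
      n_std_supported = sum(.data$std_status == "ok"),
      ceiling_ok = all(.data$dscs_replicate_log10 <=
                         .data$reference_log10 + 0.1),
      .groups = "drop")
  experiment_report("mixture_deconvolution", records, agg, seed,
                    list(noc_list = paste(noc_list, collapse = ","),
                         group_size = group_size,
                         group_cells = group_cells,
                         bulk_cells_per_donor = bulk_cells_per_donor,
                         theta = th))
}
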