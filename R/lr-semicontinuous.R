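#' Semi-continuous replicate likelihood ratio
#'
#' A drop-out/drop-in ("semi-continuous") model over one or more replicate
#' EPGs. Per locus, the likelihood under a hypothesis is the sum over
#' genotype assignments to its contributors (theta-corrected sequential
#' Balding-Nichols priors, conditioned on the known donors of both
#' hypotheses, with unobserved alleles lumped into a residual class) of
#' the product over replicates of:
#'
#' * each expected allele copy independently detected with probability
#'   `1 - d_k` for its carrying contributor `k` (a homozygote's two copies
#'   are two independent chances, so homozygote drop-out is `d_k^2`);
#' * each observed allele not carried by any contributor explained as
#'   drop-in with probability `c * freq(allele)`, at most
#'   `max_dropins` per locus per replicate;
#' * a no-drop-in factor `1 - c` when a replicate locus has no drop-in.
#'
#' Per-contributor drop-out probabilities are shared across loci and
#' maximised over `d_grid` separately under Hp and Hd (exhaustively for
#' one contributor; by deterministic coordinate ascent over the same grid
#' from several fixed starts otherwise).
#'
#' @param replicates A list of thresholded `epg` objects (or one `epg`).
#' @param hp,hd [hypothesis()] objects (NOC at most 3 each).
#' @param freqs An `allele_freqs` table.
#' @param panel A `locus_panel`.
#' @param d_grid Drop-out grid; default `seq(0.01, 0.99, by = 0.01)`. A
#'   single value fixes d (no maximisation).
#' @param dropin_rate Per-locus per-replicate drop-in probability `c`.
#' @param max_dropins Drop-in cap per locus per replicate (default 2).
#' @param loci Optional locus subset; defaults to the panel's loci.
#' @return An `lr_result` with fitted drop-out values in
#'   `nuisance_estimates`.
#' @export
semicontinuous_replicate_lr <- function(replicates, hp, hd, freqs,
                                        panel = gf_panel(),
                                        d_grid = seq(0.01, 0.99,
                                                     by = 0.01),
                                        dropin_rate = 0.0164,
                                        max_dropins = 2,
                                        loci = NULL) {
  if (inherits(replicates, "epg")) replicates <- list(replicates)
  if (hp$noc > 3 || hd$noc > 3) {
    stop("semi-continuous engine supports at most 3 contributors ",
         "(exact genotype enumeration)")
  }
  if (is.null(loci)) loci <- panel$locus
  obs <- lapply(replicates, function(e) {
    lapply(stats::setNames(loci, loci), function(loc) {
      e$allele[e$locus == loc]
    })
  })
  warn_alleles <- setdiff(
    unlist(lapply(obs, unlist)),
    freqs$allele[freqs$locus %in% loci])
  if (length(warn_alleles) > 0) {
    warning("observed allele(s) absent from the frequency table; ",
            "applying the 5/(2N) minimum-frequency policy: ",
            paste(utils::head(warn_alleles, 5), collapse = ", "))
  }
  # per-hypothesis maximised likelihood
  fit_h <- function(hyp) {
    scen <- lapply(loci, function(loc) {
      build_sc_scenario(loc, lapply(obs, function(o) o[[loc]]),
                        hyp, hp, hd, freqs, dropin_rate, max_dropins)
    })
    maximize_dropout(scen, hyp$noc, d_grid)
  }
  fp <- fit_h(hp)
  fd <- fit_h(hd)
  per <- tibble::tibble(locus = loci,
                        log10_lr = (fp$per_locus_log - fd$per_locus_log) /
                          log(10))
  nuis <- dplyr::bind_rows(
    tibble::tibble(hypothesis = "Hp",
                   contributor = seq_along(fp$d), d = fp$d),
    tibble::tibble(hypothesis = "Hd",
                   contributor = seq_along(fd$d), d = fd$d))
  lr_result(per, hp = hp, hd = hd, model = "semi_continuous",
            nuisance_estimates = nuis,
            n_replicates = length(replicates))
}

# Scenario for one locus under one hypothesis: genotype combos with
# priors, each carrying per-replicate dose bookkeeping against the
# observed alleles, plus the (d-independent) drop-in constant.
build_sc_scenario <- function(loc, obs_reps, hyp, hp, hd, freqs,
                              dropin_rate, max_dropins) {
  setup <- locus_setup(loc, unique(unlist(obs_reps)), hp, hd, freqs)
  combos <- enumerate_unknowns(hyp, setup$universe, setup$p,
                               setup$base_counts, hyp$theta)
  known_genos <- lapply(hyp$known, function(p) profile_genotype(p, loc))
  K <- hyp$noc
  out <- vector("list", length(combos))
  for (ci in seq_along(combos)) {
    genos <- c(known_genos, combos[[ci]]$genos)
    # distinct real alleles carried and per-contributor dose
    carried <- sort(unique(unlist(genos)))
    carried <- carried[carried != -1]
    dose <- matrix(0, nrow = K, ncol = length(carried))
    q_dose <- numeric(K)
    for (k in seq_len(K)) {
      for (a in genos[[k]]) {
        if (a == -1) q_dose[k] <- q_dose[k] + 1
        else {
          j <- match(a, carried)
          dose[k, j] <- dose[k, j] + 1
        }
      }
    }
    reps <- vector("list", length(obs_reps))
    ok <- TRUE
    for (r in seq_along(obs_reps)) {
      o <- obs_reps[[r]]
      in_obs <- carried %in% o
      dropin_al <- setdiff(o, carried)
      if (length(dropin_al) > max_dropins ||
          (length(dropin_al) > 0 && dropin_rate <= 0)) {
        ok <- FALSE
        break
      }
      dropin_const <- if (length(dropin_al) == 0) {
        1 - dropin_rate
      } else {
        prod(dropin_rate * allele_freq(freqs, loc, dropin_al))
      }
      # unobserved dose per contributor (incl. lumped Q copies)
      miss_dose <- q_dose +
        if (any(!in_obs)) rowSums(dose[, !in_obs, drop = FALSE]) else 0
      reps[[r]] <- list(obs_dose = dose[, in_obs, drop = FALSE],
                        miss_dose = miss_dose,
                        dropin_const = dropin_const)
    }
    if (!ok) next
    out[[ci]] <- list(prior = combos[[ci]]$prior, reps = reps)
  }
  out[!vapply(out, is.null, TRUE)]
}

# Likelihood of one locus scenario over a set of candidate d vectors
# (d: K x G matrix). Returns length-G likelihood vector.
sc_locus_lik <- function(scenario, d) {
  G <- ncol(d)
  total <- numeric(G)
  for (combo in scenario) {
    lc <- rep(combo$prior, G)
    for (rep_info in combo$reps) {
      # missing copies: prod_k d_k^miss_dose_k
      v <- rep(rep_info$dropin_const, G)
      md <- rep_info$miss_dose
      for (k in seq_along(md)) {
        if (md[k] > 0) v <- v * d[k, ]^md[k]
      }
      od <- rep_info$obs_dose
      if (ncol(od) > 0) {
        for (j in seq_len(ncol(od))) {
          w <- rep(1, G)
          for (k in seq_len(nrow(od))) {
            if (od[k, j] > 0) w <- w * d[k, ]^od[k, j]
          }
          v <- v * (1 - w)
        }
      }
      lc <- lc * v
    }
    total <- total + lc
  }
  total
}

# total log-likelihood over loci for candidate d matrix
sc_total_loglik <- function(scenarios, d) {
  ll <- 0
  for (s in scenarios) ll <- ll + log(sc_locus_lik(s, d))
  ll
}

# Maximise the joint likelihood over the drop-out grid. Exhaustive for one
# contributor; coordinate ascent over the grid for 2-3 contributors.
maximize_dropout <- function(scenarios, K, d_grid) {
  G <- length(d_grid)
  if (G == 1) {
    d_best <- rep(d_grid, K)
  } else if (K == 1) {
    ll <- sc_total_loglik(scenarios, matrix(d_grid, nrow = 1))
    d_best <- d_grid[which.max(ll)]
  } else {
    starts <- list(rep(0.3, K), rep(0.7, K))
    best_ll <- -Inf
    d_best <- starts[[1]]
    for (st in starts) {
      cur <- st
      for (sweep in 1:12) {
        changed <- FALSE
        for (k in seq_len(K)) {
          cand <- matrix(rep(cur, G), nrow = K)
          cand[k, ] <- d_grid
          ll <- sc_total_loglik(scenarios, cand)
          j <- which.max(ll)
          if (!isTRUE(all.equal(cur[k], d_grid[j]))) {
            cur[k] <- d_grid[j]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      ll_cur <- sc_total_loglik(scenarios, matrix(cur, ncol = 1))
      if (ll_cur > best_ll) { best_ll <- ll_cur; d_best <- cur }
    }
  }
  d_final <- matrix(d_best, ncol = 1)
  per_locus_log <- vapply(scenarios, function(s) {
    log(sc_locus_lik(s, d_final))
  }, 0)
  list(d = as.numeric(d_best), per_locus_log = per_locus_log)
}

#' Search a database of known non-contributors
#'
#' Computes, for each database profile, the likelihood ratio with that
#' profile as the single known contributor under Hp against `hd_unknowns`
#' unknown contributors under Hd. Engine failures are recorded per profile
#' and the search continues. Results are ordered by donor id.
#'
#' @param replicates A list of thresholded `epg` objects (or one `epg`).
#' @param database A list of `ref_profile` objects.
#' @param freqs An `allele_freqs` table.
#' @param panel A `locus_panel`.
#' @param model `"semi_continuous"` (default) or `"quantitative"`.
#' @param hd_unknowns Unknown contributors under Hd (and NOC under Hp,
#'   with the database profile substituting for one unknown).
#' @param ... Passed through to the engine.
#' @return A tibble with one row per profile: `donor_id`,
#'   `log10_lr`, `status`, and a list-column `result` of `lr_result`s.
#' @export
database_search <- function(replicates, database, freqs,
                            panel = gf_panel(),
                            model = c("semi_continuous", "quantitative"),
                            hd_unknowns = 1, ...) {
  model <- match.arg(model)
  if (length(database) == 0) stop("empty database")
  ids <- vapply(database, profile_donor_id, "")
  ord <- order(ids)
  engine <- if (model == "semi_continuous") {
    semicontinuous_replicate_lr
  } else {
    quantitative_replicate_lr
  }
  th <- freq_theta(freqs)
  hd <- hypothesis(list(), hd_unknowns, theta = th)
  rows <- purrr::map(ord, function(i) {
    hp <- hypothesis(database[[i]],
                     n_unknowns = hd_unknowns - 1, theta = th)
    res <- tryCatch(engine(replicates, hp, hd, freqs, panel, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(donor_id = ids[i], log10_lr = NA_real_,
                     status = paste("error:", conditionMessage(res)),
                     result = list(NULL))
    } else {
      tibble::tibble(donor_id = ids[i],
                     log10_lr = res$log10_lr_total,
                     status = res$status, result = list(res))
    }
  })
  dplyr::bind_rows(rows)
}
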