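#' Quantitative-model parameters
#'
#' Parameters of the simplified gamma peak-height model: `mu` is the
#' expected height (RFU) per allele copy at unit mixture share and the
#' reference fragment size; `omega` the coefficient of variation of peak
#' heights; `mix_props` the per-contributor mixture shares (sum 1);
#' `delta` the per-contributor degradation factor per 100 bp; `xi_b` and
#' `xi_f` the back/forward stutter proportions; `dropin_rate` the drop-in
#' rate. Drop-in heights follow either a uniform law up to `dropin_cap`
#' (the default, height-independent, mirroring the reference software's
#' uniform drop-in distribution for low-template work) or an exponential
#' law with decay `dropin_lambda` above the analytical threshold.
#'
#' @param mu,omega,mix_props,delta,xi_b,xi_f,dropin_rate,dropin_lambda
#'   See description.
#' @param dropin_dist `"uniform"` (default) or `"exponential"`.
#' @param dropin_cap Ceiling of the uniform drop-in height law (RFU).
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(mu = 1000, omega = 0.4, mix_props = NULL,
                         delta = NULL, xi_b = 0.08, xi_f = 0.02,
                         dropin_rate = 0.0164, dropin_lambda = 0.01,
                         dropin_dist = c("uniform", "exponential"),
                         dropin_cap = 30000) {
  dropin_dist <- match.arg(dropin_dist)
  if (!is.null(mix_props) &&
      abs(sum(mix_props) - 1) > 1e-9) {
    stop("mix_props must sum to 1")
  }
  if (xi_b + xi_f >= 1) stop("xi_b + xi_f must be < 1")
  structure(list(mu = mu, omega = omega, mix_props = mix_props,
                 delta = delta, xi_b = xi_b, xi_f = xi_f,
                 dropin_rate = dropin_rate,
                 dropin_lambda = dropin_lambda,
                 dropin_dist = dropin_dist, dropin_cap = dropin_cap),
            class = "quant_params")
}

# ---- internal likelihood ----

# Per-locus position bookkeeping for the gamma model under one hypothesis.
# Positions are the union of observed alleles, contributor alleles and
# their +/- 1 repeat stutter targets; lumped unobserved copies (Q) always
# contribute drop-out mass.
quant_locus_data <- function(loc, replicates, hyp, hp, hd, freqs, panel,
                             atv) {
  obs_al <- unique(unlist(lapply(replicates,
                                 function(e) e$allele[e$locus == loc])))
  setup <- locus_setup(loc, obs_al, hp, hd, freqs)
  combos <- enumerate_unknowns(hyp, setup$universe, setup$p,
                               setup$base_counts, hyp$theta)
  known_genos <- lapply(hyp$known, function(p) profile_genotype(p, loc))
  K <- hyp$noc
  dye <- locus_dye(panel, loc)
  at_loc <- atv[[dye]]
  pi <- match(loc, panel$locus)
  centre <- (panel$allele_min[pi] + panel$allele_max[pi]) / 2
  combo_data <- lapply(combos, function(cb) {
    genos <- c(known_genos, cb$genos)
    carried <- sort(unique(unlist(genos)))
    carried <- carried[carried != -1]
    positions <- sort(unique(c(obs_al, carried, carried - 1,
                               carried + 1)))
    dose <- matrix(0, nrow = K, ncol = length(positions))
    q_dose <- numeric(K)
    for (k in seq_len(K)) {
      for (a in genos[[k]]) {
        if (a == -1) q_dose[k] <- q_dose[k] + 1
        else dose[k, match(a, positions)] <- dose[k, match(a, positions)] + 1
      }
    }
    sizes <- allele_size(panel, loc, positions)
    obs_h <- lapply(replicates, function(e) {
      h <- rep(0, length(positions))
      pk <- e[e$locus == loc, , drop = FALSE]
      j <- match(pk$allele, positions)
      h[j[!is.na(j)]] <- pk$height[!is.na(j)]
      h
    })
    p_pos <- allele_freq(freqs, loc, positions)
    list(prior = cb$prior, dose = dose, q_dose = q_dose,
         positions = positions, sizes = sizes, obs_h = obs_h,
         p_pos = p_pos)
  })
  list(combos = combo_data, at = at_loc, K = K,
       q_size = allele_size(panel, loc, centre))
}

# log-likelihood of one locus given parameter list th
quant_locus_loglik <- function(ld, th, max_dropins = 2) {
  shape <- 1 / th$omega^2
  logs <- vapply(ld$combos, function(cb) {
    # expected pre-stutter height per position per contributor
    npos <- length(cb$positions)
    E <- numeric(npos)
    for (k in seq_len(nrow(cb$dose))) {
      degr <- th$delta[k]^((cb$sizes - 125) / 100)
      E <- E + th$mu * th$mix[k] * cb$dose[k, ] * degr
    }
    # stutter redistribution: position a receives xi_b from parent a+1
    # and xi_f from parent a-1 (one repeat unit in allele number)
    M <- (1 - th$xi_b - th$xi_f) * E
    if (th$xi_b > 0 || th$xi_f > 0) {
      for (j in seq_len(npos)) {
        up <- which(abs(cb$positions - (cb$positions[j] + 1)) < 1e-6)
        dn <- which(abs(cb$positions - (cb$positions[j] - 1)) < 1e-6)
        if (length(up)) M[j] <- M[j] + th$xi_b * E[up[1]]
        if (length(dn)) M[j] <- M[j] + th$xi_f * E[dn[1]]
      }
    }
    # lumped unobserved copies per contributor
    EQ <- sum(th$mu * th$mix * cb$q_dose *
                th$delta^((ld$q_size - 125) / 100)) *
      (1 - th$xi_b - th$xi_f)
    ll <- log(cb$prior)
    for (h in cb$obs_h) {
      n_dropin <- 0L
      for (j in seq_len(npos)) {
        if (h[j] > 0 && M[j] > 0) {
          ll <- ll + stats::dgamma(h[j], shape = shape,
                                   scale = M[j] / shape, log = TRUE)
        } else if (h[j] > 0) {
          n_dropin <- n_dropin + 1L
          if (th$dropin_rate <= 0) return(-Inf)
          ll <- ll + if (th$dropin_dist == "uniform") {
            if (h[j] > th$dropin_cap) return(-Inf)
            log(th$dropin_rate * cb$p_pos[j] /
                  (th$dropin_cap - ld$at))
          } else {
            log(th$dropin_rate * cb$p_pos[j] * th$dropin_lambda) -
              th$dropin_lambda * max(h[j] - ld$at, 0)
          }
        } else if (M[j] > 0) {
          ll <- ll + stats::pgamma(ld$at, shape = shape,
                                   scale = M[j] / shape, log.p = TRUE)
        }
      }
      if (n_dropin > max_dropins) return(-Inf)
      if (n_dropin == 0L) ll <- ll + log(1 - th$dropin_rate)
      if (EQ > 0) {
        ll <- ll + stats::pgamma(ld$at, shape = shape,
                                 scale = EQ / shape, log.p = TRUE)
      }
    }
    ll
  }, 0)
  m <- max(logs)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(logs - m)))
}

# parameter vector transforms
quant_unpack <- function(x, K, qinit, degradation_max) {
  n_mix <- K - 1
  i <- 0
  mu <- exp(x[i + 1]); i <- i + 1
  omega <- 0.05 + 1.95 * stats::plogis(x[i + 1]); i <- i + 1
  mix <- if (n_mix == 0) 1 else {
    w <- exp(pmin(x[i + seq_len(n_mix)], 30))
    i <- i + n_mix
    c(w, 1) / (sum(w) + 1)
  }
  k_deg <- degradation_max * stats::plogis(x[i + seq_len(K)])
  delta <- exp(-100 * k_deg)   # factor per 100 bp
  i <- i + K
  xi_b <- 0.3 * stats::plogis(x[i + 1]); i <- i + 1
  xi_f <- 0.15 * stats::plogis(x[i + 1])
  list(mu = mu, omega = omega, mix = mix, delta = delta,
       xi_b = xi_b, xi_f = xi_f, dropin_rate = qinit$dropin_rate,
       dropin_lambda = qinit$dropin_lambda,
       dropin_dist = qinit$dropin_dist, dropin_cap = qinit$dropin_cap)
}

quant_pack_init <- function(K, qinit, mu_init) {
  n_mix <- K - 1
  mix0 <- if (is.null(qinit$mix_props)) rep(1 / K, K) else qinit$mix_props
  c(log(mu_init),
    stats::qlogis(pmin(pmax((qinit$omega - 0.05) / 1.95, 0.02), 0.98)),
    if (n_mix > 0) log(pmin(pmax(mix0[seq_len(n_mix)] / mix0[K],
                                 1e-3), 1e3)),
    rep(stats::qlogis(0.02), K),  # decay rate near 0 (no degradation)
    stats::qlogis(pmin(pmax(qinit$xi_b / 0.3, 0.02), 0.98)),
    stats::qlogis(pmin(pmax(qinit$xi_f / 0.15, 0.02), 0.98)))
}

# maximise the quantitative likelihood under one hypothesis
quant_fit_h <- function(replicates, hyp, hp, hd, freqs, panel, atv,
                        qinit, n_starts, degradation_max, seed, loci) {
  lds <- lapply(loci, function(loc) {
    quant_locus_data(loc, replicates, hyp, hp, hd, freqs, panel, atv)
  })
  K <- hyp$noc
  heights <- unlist(lapply(replicates, function(e) e$height))
  mu_init <- if (is.null(qinit$mu) || is.na(qinit$mu)) {
    max(stats::median(heights), 100)
  } else qinit$mu
  negll <- function(x) {
    th <- quant_unpack(x, K, qinit, degradation_max)
    ll <- 0
    for (ld in lds) {
      l1 <- quant_locus_loglik(ld, th)
      if (!is.finite(l1)) return(1e12)
      ll <- ll + l1
    }
    -ll
  }
  if (is.null(qinit$mix_props) && K > 1 && length(hyp$known) == K) {
    # initialise shares from peaks unique to each known contributor
    shares <- vapply(seq_len(K), function(k) {
      own <- hyp$known[[k]]
      others <- unlist(lapply(hyp$known[-k], function(p) {
        paste(p$locus, c(p$a1, p$a2))
      }))
      tot <- 0
      for (e in replicates) {
        key <- paste(e$locus, e$allele)
        mine <- key %in% paste(own$locus, c(own$a1, own$a2)) &
          !key %in% others
        tot <- tot + sum(e$height[mine])
      }
      tot
    }, 0)
    if (all(shares > 0)) qinit$mix_props <- shares / sum(shares)
  }
  x0 <- quant_pack_init(K, qinit, mu_init)
  seeds <- derive_seeds(seed, n_starts)
  maxit <- if (K > 1) 1000 else 500
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    start <- if (s == 1) x0 else x0 + stats::rnorm(length(x0), 0, 0.5)
    fit <- tryCatch(stats::optim(start, negll, method = "Nelder-Mead",
                                 control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(list(status = "FAIL"))
  th <- quant_unpack(best$par, K, qinit, degradation_max)
  per_locus_log <- vapply(lds, function(ld) quant_locus_loglik(ld, th), 0)
  list(status = "ok", loglik = -best$value, per_locus_log = per_locus_log,
       params = th)
}

#' Quantitative (gamma peak-height) replicate likelihood ratio
#'
#' A simplified continuous model in the style of maximum-likelihood
#' quantitative genotyping software: each allele position's observed
#' height is gamma distributed with mean
#' `sum_k mu * mix_k * dose_k * delta_k^((size - 125)/100)` redistributed
#' by back/forward stutter proportions; expected-but-absent positions
#' contribute the gamma mass below the dye's analytical threshold
#' (drop-out); observed positions with zero expectation contribute
#' drop-in (rate times a uniform or exponential height law). The
#' likelihood is maximised over `mu`, `omega`, mixture proportions,
#' per-contributor degradation (an exponential decay rate per bp, capped
#' at `degradation_max`) and stutter proportions,
#' separately under each hypothesis, with `n_starts` restarts. Unknown
#' contributor genotypes are marginalised with the same theta-corrected
#' priors as the semi-continuous engine. If no start converges the result
#' has status `"FAIL"` rather than a silent number.
#'
#' @inheritParams semicontinuous_replicate_lr
#' @param qinit A [quant_params()] initialisation (drop-in rate and
#'   lambda are fixed at their `qinit` values, not optimised).
#' @param n_starts Optimiser restarts (default 3).
#' @param at An `at_thresholds` table.
#' @param degradation_max Cap on the per-bp exponential degradation
#'   decay rate (default 0.1, the reference software's setting for
#'   low-template work).
#' @param seed Seed for the deterministic restart jitter.
#' @return An `lr_result` (status `"FAIL"` on model failure).
#' @export
quantitative_replicate_lr <- function(replicates, hp, hd, freqs,
                                      panel = gf_panel(),
                                      qinit = quant_params(),
                                      n_starts = 3,
                                      at = at_thresholds(),
                                      degradation_max = 0.1,
                                      seed = 1, loci = NULL) {
  if (inherits(replicates, "epg")) replicates <- list(replicates)
  if (hp$noc > 2 || hd$noc > 2) {
    stop("quantitative engine supports at most 2 contributors")
  }
  if (is.null(loci)) loci <- panel$locus
  atv <- at_vector(at)
  fp <- quant_fit_h(replicates, hp, hp, hd, freqs, panel, atv, qinit,
                    n_starts, degradation_max, seed, loci)
  fd <- quant_fit_h(replicates, hd, hp, hd, freqs, panel, atv, qinit,
                    n_starts, degradation_max, seed, loci)
  if (identical(fp$status, "FAIL") || identical(fd$status, "FAIL")) {
    return(lr_result(tibble::tibble(locus = loci, log10_lr = NA_real_),
                     hp = hp, hd = hd, model = "quantitative",
                     n_replicates = length(replicates),
                     status = "FAIL"))
  }
  per <- tibble::tibble(locus = loci,
                        log10_lr = (fp$per_locus_log - fd$per_locus_log) /
                          log(10))
  nuis <- dplyr::bind_rows(
    tibble::tibble(hypothesis = "Hp", mu = fp$params$mu,
                   omega = fp$params$omega,
                   mix = list(fp$params$mix),
                   delta = list(fp$params$delta),
                   xi_b = fp$params$xi_b, xi_f = fp$params$xi_f),
    tibble::tibble(hypothesis = "Hd", mu = fd$params$mu,
                   omega = fd$params$omega,
                   mix = list(fd$params$mix),
                   delta = list(fd$params$delta),
                   xi_b = fd$params$xi_b, xi_f = fd$params$xi_f))
  lr_result(per, hp = hp, hd = hd, model = "quantitative",
            nuisance_estimates = nuis,
            n_replicates = length(replicates))
}

#' Fit the quantitative model with all contributors known
#'
#' Maximum-likelihood fit of the gamma peak-height model for a fully
#' specified contributor set (no genotype marginalisation). Used for
#' parameter-recovery studies, e.g. recovering mixture proportions from
#' simulated two-person subsamples.
#'
#' @param replicates A list of thresholded `epg` objects (or one `epg`).
#' @param contributors A list of `ref_profile` objects.
#' @param freqs An `allele_freqs` table.
#' @inheritParams quantitative_replicate_lr
#' @return A tibble of fitted parameters (one row; `mix` and `delta` are
#'   list-columns), or a zero-row tibble on failure.
#' @export
quant_fit <- function(replicates, contributors, freqs,
                      panel = gf_panel(), qinit = quant_params(),
                      n_starts = 3, at = at_thresholds(),
                      degradation_max = 0.1, seed = 1, loci = NULL) {
  if (inherits(replicates, "epg")) replicates <- list(replicates)
  if (is.null(loci)) loci <- panel$locus
  th0 <- freq_theta(freqs)
  h <- hypothesis(contributors, 0, theta = th0)
  fit <- quant_fit_h(replicates, h, h, h, freqs, panel, at_vector(at),
                     qinit, n_starts, degradation_max, seed, loci)
  if (identical(fit$status, "FAIL")) {
    return(tibble::tibble(mu = double(), omega = double(),
                          mix = list(), delta = list(),
                          xi_b = double(), xi_f = double(),
                          loglik = double()))
  }
  tibble::tibble(mu = fit$params$mu, omega = fit$params$omega,
                 mix = list(fit$params$mix),
                 delta = list(fit$params$delta),
                 xi_b = fit$params$xi_b, xi_f = fit$params$xi_f,
                 loglik = fit$loglik)
}
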