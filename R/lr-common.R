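#' Define a hypothesis about the contributors to a profile
#'
#' A hypothesis names the known contributors (reference profiles) and the
#' number of unknown, unrelated contributors; the number of contributors
#' (NOC) is their sum. Theta is the subpopulation co-ancestry coefficient
#' used for the theta-corrected genotype probabilities of the unknowns.
#'
#' @param known A list of `ref_profile` objects (or a single one).
#' @param n_unknowns Count of unknown contributors.
#' @param theta Co-ancestry coefficient in `[0, 0.5)`.
#' @return A list of class `hypothesis`.
#' @export
hypothesis <- function(known = list(), n_unknowns = 0, theta = 0.01) {
  if (inherits(known, "ref_profile")) known <- list(known)
  noc <- length(known) + n_unknowns
  if (noc < 1) stop("a hypothesis needs at least one contributor")
  if (theta < 0 || theta >= 0.5) stop("theta must lie in [0, 0.5)")
  structure(list(known = known, n_unknowns = as.integer(n_unknowns),
                 noc = as.integer(noc), theta = theta),
            class = "hypothesis")
}

#' @export
print.hypothesis <- function(x, ...) {
  ids <- vapply(x$known, profile_donor_id, "")
  cat(sprintf("<hypothesis> %s + %d unknown(s), theta = %g\n",
              if (length(ids)) paste(ids, collapse = " + ") else "(none)",
              x$n_unknowns, x$theta))
  invisible(x)
}

# Balding-Nichols sequential sampling probability of drawing allele a
# given n alleles already observed, n_a of them copies of a.
bn_next_prob <- function(n_a, n, p_a, theta) {
  (n_a * theta + (1 - theta) * p_a) / (1 + (n - 1) * theta)
}

#' Theta-corrected single-locus match probability
#'
#' The probability that a random member of the subpopulation shares the
#' genotype, conditional on having observed it once (Balding-Nichols):
#' heterozygotes
#' `2[t+(1-t)p_i][t+(1-t)p_j] / ((1+t)(1+2t))`, homozygotes
#' `[3t+(1-t)p_i][2t+(1-t)p_i] / ((1+t)(1+2t))` with `t` the theta of the
#' frequency table. At `t = 0` these reduce to `2 p_i p_j` and `p_i^2`.
#'
#' @param genotype Numeric pair of allele designations (equal pair =
#'   homozygote).
#' @param freqs An `allele_freqs` table (supplies theta and the
#'   minimum-frequency policy).
#' @param locus Locus name.
#' @return The match probability.
#' @export
locus_match_probability <- function(genotype, freqs, locus) {
  stopifnot(length(genotype) == 2)
  th <- freq_theta(freqs)
  p <- allele_freq(freqs, locus, genotype)
  denom <- (1 + th) * (1 + 2 * th)
  if (genotype[1] == genotype[2]) {
    (3 * th + (1 - th) * p[1]) * (2 * th + (1 - th) * p[1]) / denom
  } else {
    2 * (th + (1 - th) * p[1]) * (th + (1 - th) * p[2]) / denom
  }
}

#' Single-source profile likelihood ratio
#'
#' For a clean full single-source profile matching a reference, the
#' likelihood ratio is the inverse of the profile's random match
#' probability: per locus `log10 LR = -log10(match probability)`, summed
#' over loci.
#'
#' @param profile A `ref_profile`.
#' @param freqs An `allele_freqs` table.
#' @param loci Optional subset of loci (partial-profile mode); defaults to
#'   every locus in the profile.
#' @return An `lr_result`.
#' @export
single_source_profile_lr <- function(profile, freqs, loci = NULL) {
  use <- if (is.null(loci)) profile$locus else {
    missing <- setdiff(loci, profile$locus)
    if (length(missing) > 0) {
      stop("profile missing loci: ", paste(missing, collapse = ", "))
    }
    loci
  }
  per <- purrr::map_dfr(use, function(loc) {
    mp <- locus_match_probability(profile_genotype(profile, loc), freqs,
                                  loc)
    tibble::tibble(locus = loc, log10_lr = -log10(mp))
  })
  hp <- hypothesis(profile, 0, theta = freq_theta(freqs))
  hd <- hypothesis(list(), 1, theta = freq_theta(freqs))
  lr_result(per, hp = hp, hd = hd, model = "single_source",
            n_replicates = 0L)
}

#' Likelihood-ratio result container
#'
#' @param per_locus Tibble with columns `locus`, `log10_lr`.
#' @param hp,hd The hypotheses compared.
#' @param model Engine label.
#' @param nuisance_estimates Optional tibble of fitted nuisance parameters.
#' @param n_replicates Number of replicates combined.
#' @param status `"ok"` or `"FAIL"` (model validation failure).
#' @return A list of class `lr_result`. A likelihood ratio of zero is
#'   stored as `log10_lr_total = -Inf`.
#' @export
lr_result <- function(per_locus, hp, hd, model,
                      nuisance_estimates = NULL, n_replicates = 1L,
                      status = "ok") {
  total <- if (status == "FAIL") NA_real_ else sum(per_locus$log10_lr)
  structure(list(log10_lr_total = total, per_locus = per_locus,
                 hp = hp, hd = hd, model = model,
                 nuisance_estimates = nuisance_estimates,
                 n_replicates = as.integer(n_replicates),
                 status = status),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  if (x$status == "FAIL") {
    cat(sprintf("<lr_result> %s: FAIL (model validation failure)\n",
                x$model))
  } else {
    cat(sprintf("<lr_result> %s: log10(LR) = %.3f over %d loci (%d replicate%s)\n",
                x$model, x$log10_lr_total, nrow(x$per_locus),
                x$n_replicates, ifelse(x$n_replicates == 1, "", "s")))
  }
  invisible(x)
}

#' @export
tidy.lr_result <- function(x, ...) x$per_locus

#' @export
glance.lr_result <- function(x, ...) {
  tibble::tibble(log10_lr_total = x$log10_lr_total, model = x$model,
                 status = x$status, n_replicates = x$n_replicates,
                 noc_hp = x$hp$noc, noc_hd = x$hd$noc)
}

#' Render a log10 LR for plotting/export
#'
#' Likelihood ratios of zero are stored as `-Inf`; figures substitute a
#' finite sentinel (−350 or −50 by convention).
#'
#' @param log10_lr Numeric vector.
#' @param sentinel Value substituted for `-Inf` (default −350).
#' @return Numeric vector with `-Inf`/`NA` replaced by `sentinel`.
#' @export
render_log10_lr <- function(log10_lr, sentinel = -350) {
  out <- log10_lr
  out[!is.finite(out)] <- sentinel
  out
}

# ---- genotype enumeration with theta-corrected sequential priors ----

# Conditioning allele counts: each distinct known donor (across both
# hypotheses) contributes their two alleles at the locus.
cond_counts <- function(loc, hp, hd) {
  profs <- c(hp$known, hd$known)
  if (length(profs) == 0) return(numeric(0))
  ids <- vapply(profs, profile_donor_id, "")
  profs <- profs[!duplicated(ids)]
  al <- unlist(lapply(profs, function(p) profile_genotype(p, loc)))
  tab <- table(al)
  stats::setNames(as.numeric(tab), names(tab))
}

# Enumerate genotype assignments for the unknowns of `hyp` at one locus.
# `universe` is the numeric allele set for enumeration; the lumped
# unobserved allele Q is coded as -1 with residual frequency. Returns a
# list of combos: list(genos = list of length-2 vectors, prior).
enumerate_unknowns <- function(hyp, universe, p_universe, base_counts,
                               theta) {
  n_unknowns <- hyp$n_unknowns
  if (n_unknowns == 0) {
    return(list(list(genos = list(), prior = 1)))
  }
  m <- length(universe)
  pairs <- list()
  for (i in seq_len(m)) for (j in i:m) {
    pairs[[length(pairs) + 1L]] <- c(universe[i], universe[j])
  }
  counts0 <- stats::setNames(rep(0, m), as.character(universe))
  for (nm in names(base_counts)) {
    if (nm %in% names(counts0)) counts0[nm] <- base_counts[[nm]]
  }
  n0 <- sum(base_counts)
  p_named <- stats::setNames(p_universe, as.character(universe))

  geno_prior <- function(g, counts, n) {
    k1 <- as.character(g[1]); k2 <- as.character(g[2])
    if (g[1] == g[2]) {
      bn_next_prob(counts[[k1]], n, p_named[[k1]], theta) *
        bn_next_prob(counts[[k1]] + 1, n + 1, p_named[[k1]], theta)
    } else {
      2 * bn_next_prob(counts[[k1]], n, p_named[[k1]], theta) *
        bn_next_prob(counts[[k2]], n + 1, p_named[[k2]], theta)
    }
  }

  combos <- list()
  recurse <- function(k, genos, counts, n, prior) {
    if (k > n_unknowns) {
      combos[[length(combos) + 1L]] <<- list(genos = genos, prior = prior)
      return(invisible())
    }
    for (g in pairs) {
      pr <- geno_prior(g, counts, n)
      if (pr <= 0) next
      counts2 <- counts
      counts2[[as.character(g[1])]] <- counts2[[as.character(g[1])]] + 1
      counts2[[as.character(g[2])]] <- counts2[[as.character(g[2])]] + 1
      recurse(k + 1, c(genos, list(g)), counts2, n + 2, prior * pr)
    }
  }
  recurse(1L, list(), counts0, n0, 1)
  combos
}

# Locus enumeration setup shared by both engines: allele universe
# (observed + known alleles of both hypotheses + lumped Q = -1),
# frequencies with residual mass on Q, conditioning counts.
locus_setup <- function(loc, obs_alleles, hp, hd, freqs) {
  known_al <- unlist(lapply(c(hp$known, hd$known), function(p) {
    profile_genotype(p, loc)
  }))
  real <- sort(unique(c(obs_alleles, known_al)))
  p_real <- if (length(real)) allele_freq(freqs, loc, real) else numeric(0)
  min_f <- 5 / (2 * freq_db_size(freqs))
  p_q <- max(1 - sum(p_real), min_f)
  universe <- c(real, -1)
  p_universe <- c(p_real, p_q)
  list(universe = universe, p = p_universe,
       base_counts = cond_counts(loc, hp, hd))
}
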