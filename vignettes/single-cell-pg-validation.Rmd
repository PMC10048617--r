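---
title: "Validating probabilistic genotyping for single-cell STR profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating probabilistic genotyping for single-cell STR profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpg)
```

## The problem

Direct single-cell subsampling (DSCS) deconvolutes a forensic DNA mixture
by collecting one to five cells at a time from the stain and amplifying
each subsample separately. Every subsample then comes from one donor (or
a two-donor "mini-mixture"), so mixture complexity collapses — at the
price of extreme low-template artefacts: allele drop-out, gross
heterozygote imbalance, elevated stutter of several types, drop-in, and
detector saturation at high cycle numbers. Probabilistic genotyping (PG)
of such data needs its own calibration (thresholds, stutter files,
drop-in rate, variance model) and its own validation experiments.

`strpg` implements that workflow end to end on synthetic data: a
generator for low-template electropherograms (EPGs) with the artefact
structure above, the calibration estimators, two likelihood-ratio (LR)
engines with replicate support and Balding–Nichols theta correction, and
the validation experiment designs (sensitivity/specificity against a
non-contributor database, number-of-contributors misspecification,
replicate misclassification, and mixture deconvolution).

## The models

### Calibration estimators

* **Analytical threshold (AT).** Per dye,
  `AT = 2 * (highest baseline peak - lowest trough)` over a set of
  negative controls. Monotone in the control set by construction.
* **Stutter.** For each locus and stutter type (back, forward,
  double-back, half-back, half-forward, −1.5-repeat), the stutter ratio
  `SR = stutter height / parent height` is regressed on parent allele
  number. A locus switches from a linear fit to a plain mean when fewer
  than three distinct parent alleles are seen or the slope is not
  significant at 0.05. Predictions are truncated to `[0, cap]` with
  caps 0.7/0.7/0.3/0.5/0.15/0.15. Observations are only taken where the
  stutter position receives product from exactly one (parent, type)
  source, the position is not itself a true allele, and the ratio does
  not exceed the cap — ratios above the cap are, by the cap's
  definition, not stutter.
* **Drop-in.** `rate = events / (loci x controls)`, reported as the
  exact quotient. At most two surviving peaks per control count as
  drop-in; more flags contamination. The suggested cap is the smallest
  round thousand RFU above the highest observed drop-in height.
* **Saturation.** For simple-repeat loci, the expected parent height is
  reconstructed from its back stutter, `Ea = stutter height / SR`,
  which is immune to detector clipping because stutter is proportional
  to true product. Pairs `(Oa, Ea)` are binned by observed height in
  2,000-RFU bins; saturation is the first bin from which the median
  `Oa/Ea` stays below `1 - 0.10` for all later bins. Both the tolerance
  and the bin width are configurable; they operationalise "consistent
  divergence".
* **Heterozygote balance.** With `Hb` the larger-size over smaller-size
  sister peak ratio and `APH` their mean, the variance scale is
  `C^2 = median((log10 Hb)^2 * APH) / qchisq(0.5, 1)`; the chi-square
  median rescaling makes the median-based statistic a consistent
  estimator of the variance of `log10 Hb` at unit APH under
  `log10 Hb ~ N(0, C^2/APH)`. Bounds are `±k sqrt(C^2/APH)`; `k = 1.96`
  gives the 95% band (a doubled `2 × 1.96` convention is available).
  Note that because `C^2` is APH-normalised, it is roughly invariant to
  template amount within one protocol; the broadening of DSCS bounds
  shows against a *standard-analysis* configuration, not between 1 and
  5 cells of the same single-cell protocol.

### Likelihood-ratio engines

Both engines compare `Hp` (named contributors, possibly plus unknowns)
with `Hd` (unknowns), with unknown genotype probabilities from the
Balding–Nichols sequential sampling formula conditioned on the alleles
of every profiled (known) individual in the case. This makes the
single-source case reproduce the classic theta-corrected match
probabilities exactly, e.g. heterozygotes
`2[θ+(1−θ)p_i][θ+(1−θ)p_j]/((1+θ)(1+2θ))`. Unobserved alleles are
lumped into a residual class, which is exact for the semi-continuous
model. The total log10 LR is always the sum of per-locus terms.

* **Semi-continuous engine** (drop-out/drop-in, replicate-aware). Each
  expected allele copy is detected with probability `1 - d_k` for its
  carrying contributor (homozygote drop-out is `d_k^2`); unexplained
  observed alleles are drop-in with probability `c * freq(a)`, at most
  two per locus per replicate, with a `(1 - c)` factor when none.
  Per-contributor `d` is shared across loci and maximised on the grid
  `0.01..0.99` under each hypothesis separately — exhaustively for one
  contributor, by deterministic coordinate ascent over the same grid
  from fixed starts for two or three (exact exhaustion over the joint
  grid is not tractable at NOC 3). Because it has no stutter model,
  profiles should have all modeled stutter types filtered out first
  (`filter_unmodeled_stutter()`), mirroring how stutter-blind engines
  are fed manually filtered data.
* **Quantitative engine** (gamma peak heights, MLE). Observed heights
  are gamma with mean
  `Σ_k mu · mix_k · dose_k · delta_k^((size−125)/100)`, redistributed
  by back/forward stutter proportions; missing-but-expected positions
  contribute the gamma mass below the dye AT; unexplained peaks are
  drop-in with a uniform height law up to a 30,000-RFU cap by default
  (the height-independent choice made for low-template work after
  drop-in heights fit no gamma law; an exponential law is available).
  Degradation is an exponential decay per bp, capped at 0.1 — the scale
  on which reference software expresses its "degradation max"; a
  multiplicative floor of 0.9 per 100 bp cannot express an 80% height
  loss and was rejected. The likelihood is maximised by Nelder–Mead
  with three deterministic restarts; if no start yields a finite
  optimum the result is a `FAIL` status, never a silent number.
  Contributor counts are capped at two (the mini-mixture regime);
  five- and six-person bulk analysis is refused outright, as bulk PG is
  only recommended up to four contributors.

## The synthetic-data generator

The generator defines the study conditions and is not tuned per
experiment:

* **Peak heights.** Each allele copy in each cell contributes an
  independent log-normal height with mean 2,000 RFU (at the 125-bp
  reference size) and coefficient of variation 12. The extreme CV is
  deliberate: single-copy PCR at 32 cycles is famously dispersed, and
  it makes drop-out *emergent* — an allele drops when its realised
  height lands under the dye threshold — rather than an independent
  coin flip, so imbalance and drop-out co-occur as they do in real
  single-cell EPGs (about 24% of alleles drop at 1 cell, almost none
  at 5, and occasional saturation appears above 5 cells). Contributions
  sum over cells and shared alleles; a mean-one log-normal per-locus
  amplification-efficiency factor (sd 0.3) is shared within a locus.
* **Stutter.** Every type is generated from the configured stutter
  model with truncated-Gaussian ratio noise; the default back-stutter
  line for D16S539 is `SR = 0.0177·allele − 0.1249` and other loci use
  the same slope anchored to SR ≈ 0.085 at their central allele.
* **Drop-in** occurs per locus at rate 0.0164 with heights floored at
  the dye threshold and capped at 5,000 RFU (truncated exponential by
  default, uniform available). **Degradation** scales heights by
  `δ^((size−125)/100)`; **inhibition** multiplies named loci;
  everything is clipped at 30,000 RFU.
* **Negative controls** summarise per-dye Gaussian baseline noise
  (sd 5 RFU over 500 scan points), which puts the estimated ATs in the
  50–90 RFU range typical of a five-dye kit, plus any drop-in peaks.

What it does not emulate: PCR chemistry per cycle, pull-up/spikes,
inter-locus size-dependent amplification trends beyond degradation, or
real population allele frequencies (the shipped frequency table is
synthetic, Dirichlet-drawn over each locus's allele range). Passing
tests therefore demonstrate internal consistency of the pipeline under
controlled conditions, not concordance with any laboratory's casework.

## Worked example

```{r example, eval = FALSE}
panel <- gf_panel()
freqs <- synthetic_frequencies(panel, seed = 7)
cfg   <- sim_config()

donor <- sample_reference_profiles(freqs, 1, seed = 3)[[1]]
e <- simulate_subsample(list(list(profile = donor, cells = 1L)),
                        cfg, panel, seed = 11)
e <- filter_unmodeled_stutter(e, cfg$stutter, names(stutter_offsets()))

hp <- hypothesis(donor, 0, theta = 0.01)
hd <- hypothesis(list(), 1, theta = 0.01)
semicontinuous_replicate_lr(e, hp, hd, freqs, panel)
#> <lr_result> semi_continuous: log10(LR) = 19.674 over 21 loci (1 replicate)
single_source_profile_lr(donor, freqs)
#> <lr_result> single_source: log10(LR) = 31.618 over 21 loci (0 replicates)
```

A single cell already yields a strongly inclusionary LR; combining
replicates recovers most of the distance to the `log10(1/RMP)` ceiling
(31.6 here), which no replicate analysis can exceed.

## Numerical and design choices

* Peaks exactly at the AT are retained (`>=`), matching common analysis
  software; allele designations compare with a 0.05-repeat tolerance.
* Unseen alleles receive the `5/(2N)` minimum frequency (N = 1000 by
  default).
* LR = 0 is stored as `-Inf`; `render_log10_lr()` substitutes the
  figure sentinels (−350/−50) only for display.
* Drop-out grids, caps, thresholds (0 and 6), replicate group sizes
  (3–5, mean 4), and the screening rule for replicate membership
  (individual log10 LR > 1) are fixed named defaults, all overridable.
* Optimiser restarts and every stochastic experiment derive child seeds
  deterministically from the run seed by indexed splitting, so reports
  are byte-reproducible.
* Experiment sizes in the shipped tests are scaled-down versions of the
  full designs (e.g. 20+ replicate groups rather than hundreds of
  subsamples, a 100-profile non-contributor database over 10 seeds
  rather than 1,000 profiles); the designs themselves accept the
  full-scale counts.
* The perturbation-robustness study (degradation −80%/−5%, inhibition
  −40% at four loci, 15,000-RFU drop-in) evaluates a full-profile
  3-cell subsample whose peaks survive re-thresholding after the
  harshest perturbation — the same good-quality regime as the original
  experiment; on partial subsamples degradation genuinely removes
  alleles and the LR rightly falls.
* Mixture-share recovery at single-cell template is wide per simulation
  (the generator's height CV dominates); the recovery claim made and
  tested is central (mean/median over 50 simulations within ±0.15),
  with per-simulation spread reported, not hidden.

## Known limitations

* The engines are deterministic/MLE stand-ins for MCMC-based
  commercial systems: no posterior genotype weights, no informative
  variance priors, no per-locus amplification efficiency in the
  quantitative model. Consequences are visible and documented — e.g.
  a heterozygote drop-out with a high surviving sister yields a
  strongly negative but finite LR here, where a calibrated-variance
  MCMC system reports LR = 0; the exact-zero behaviour appears in this
  package when unexplained peaks exceed the drop-in allowance.
* The semi-continuous engine requires stutter-filtered input; the
  quantitative engine models back/forward stutter only.
* Exact genotype enumeration caps the semi-continuous engine at three
  contributors and the quantitative engine at two.
* All validation percentages produced here describe the synthetic
  conditions; the original laboratory's empirical percentages depend on
  its cells and instrument and are not reproduction targets.
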