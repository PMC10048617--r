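# strpg

Validation toolkit for probabilistic genotyping (PG) of short tandem
repeat (STR) profiles from **single or few cells**.

Direct single-cell subsampling deconvolutes a forensic DNA mixture by
genotyping 1–5-cell subsamples individually, so each subsample is single
source or a simple two-person "mini-mixture". The price is severe
low-template behaviour: allele drop-out, extreme heterozygote imbalance
(`Hb`), elevated stutter of six types, drop-in, degradation, inhibition
and detector saturation. `strpg` provides, for that regime:

* a **synthetic EPG generator** with emergent drop-out (a peak drops
  when its realised height lands under the dye's analytical threshold),
  per-type stutter, drop-in, degradation/inhibition perturbations and
  30,000-RFU saturation clipping;
* **calibration estimators**: per-dye analytical thresholds
  `AT = 2(highest peak − lowest trough)`; per-locus stutter-ratio
  regressions `SR ~ allele number` with per-type maximum-SR caps;
  drop-in rate as the exact quotient `events / (loci × samples)` with a
  cap suggestion; instrument saturation from the divergence of observed
  vs stutter-reconstructed expected heights (`Ea = stutter/SR`); and
  heterozygote-balance variance bounds `±1.96·sqrt(C²/APH)` with
  `C²` the 50th percentile of the APH-scaled `log10 Hb` variance;
* two **likelihood-ratio engines** with replicate support and
  Balding–Nichols theta correction
  (`2[θ+(1−θ)p_i][θ+(1−θ)p_j]/((1+θ)(1+2θ))` for heterozygotes): a
  semi-continuous drop-out/drop-in model maximised over a drop-out
  grid, and a quantitative gamma peak-height MLE with stutter,
  degradation and drop-in terms; plus non-contributor **database
  search**;
* **validation experiment harnesses**: sensitivity/specificity at the
  log10(LR) thresholds 0 and 6, number-of-contributors
  misspecification (N±1), replicate misclassification, and mixture
  deconvolution against the `log10(1/RMP)` reference ceiling.

Everything is tibble-first: EPGs, frequency tables, stutter models and
reports are tibbles (with metadata attributes), results have
`tidy()`/`glance()` methods, and `autoplot()`/`plot_hb_bounds()` give
the standard displays.

## Worked example

```r
library(strpg)

panel <- gf_panel()                            # 21 autosomal loci
freqs <- synthetic_frequencies(panel, seed = 7)
cfg   <- sim_config()                          # study-condition defaults

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

A single cell gives a strongly inclusionary `log10 LR ≈ 20` against the
donor; the full-profile ceiling `log10(1/RMP) ≈ 31.6` is approached by
combining same-donor subsamples with the replicate engine (joint
likelihood across replicates), which is the core of the DSCS workflow.

Calibration on simulated material:

```r
negs <- lapply(1:35, function(i) simulate_negative_control(cfg, panel, seed = i))
subs <- lapply(1:75, function(i)
  simulate_subsample(list(list(profile = donor, cells = 1 + i %% 5)),
                     cfg, panel, seed = 100 + i))
cal <- calibrate(negs, subs, rep(list(donor), 75), panel)
glance(cal)
```

A thin CLI over the same functions ships in `inst/cli/strpg.R`
(`simulate`, `calibrate`, `lr`, `validate <design>`), each writing
delimited records plus a run manifest.

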