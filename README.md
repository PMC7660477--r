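# maptrace

Quantitative analysis pipeline for studies of microtubule-dependent transport
and neurodevelopment in tubulin-mutant mouse models. A recurrent α-tubulin
missense mutation (R402H) is thought to act as a gain of function that
perturbs the binding of microtubule-associated proteins (MAPs), with
downstream defects in dynein-mediated transport and neuronal migration.
Characterising such a model takes four quantitative workflows, and maptrace
implements each of them as tested, reusable R functions, together with seeded
synthetic-data generators that provide known ground truth for every stage:

1. **Lysosome trafficking from kymographs** — traced time-position paths are
   segmented into directional runs (movement sustained for at least 3 frames;
   a run ends at the next change of state), tracks are classified
   anterograde / retrograde / bidirectional / immobile, and retrograde
   metrics (run length, per-run speed, total distance toward the soma) are
   compared between genotypes by chi-square and Mann-Whitney tests. A
   three-state continuous-time Markov model (run / pause / run, exponential
   dwells, log-normal speeds) generates tracks whose ground-truth median
   retrograde run lengths are calibrated to the study conditions
   (2.52 µm control vs 1.91 µm mutant).
2. **Microtubule co-sedimentation proteomics** — protein-level TMT 10-plex
   reporter tables with a paired littermate design are median-normalized and
   tested with an empirical-Bayes **moderated paired t** implemented in the
   package: per-protein variances s² (d = n−1 df) are shrunk toward a prior
   s0² with d0 prior df estimated by moment matching on log sample variances,
   t = mean(ratio)/√(s̃²/n) with s̃² = (d0·s0² + d·s²)/(d0+d) on d0+d df.
   Benjamini-Hochberg step-up FDR and a candidate cascade (all quantified →
   p < 0.01 → FDR 5% → known direct microtubule binders: VAPA, VAPB, REEP1,
   EZR, PRNP, KIF5C, DYNC1I1) reproduce the filter pyramid, plus
   hypergeometric gene-set enrichment on GMT files.
3. **Binned laminar distributions** — per-animal cell counts over ordered
   region schemes (ten cortical depth bins, hippocampal or cerebellar layers,
   electroporation zones) analysed by a two-way mixed ANOVA
   (group × region, animal as the repeated factor) with per-region Sidak or
   Tukey contrasts and a Shapiro-Wilk-gated total-count comparison.
4. **qPCR relative quantification** — efficiency-corrected relative
   expression E^(−ΔCt) against the geometric mean of reference-gene Cts
   (Hprt, Tfrc, Pgk1 by default), technical-replicate averaging, group fold
   changes and gated group tests; a Pfaffl-ratio variant is a flag.

A statistics core (chi-square without continuity correction, exact and
asymptotic Mann-Whitney, Kruskal-Wallis with Dunn contrasts,
Bonferroni/Sidak/BH adjustment, gated t tests) backs all modules and
serializes every result to JSON with its inputs' n and options.

## Worked example

```r
library(maptrace)

cfg <- track_sim_config(n_tracks_per_group = 60, seed = 101)
sim <- simulate_tracks(cfg)          # 361 samples per track: 3 min at 0.5 s
rep <- compare_trafficking(sim$tracks)
print(rep)
```

```
Lysosome trafficking comparison: control vs mutant
  tracks classified: 120
        anterograde retrograde bidirectional immobile
control           0          0            41       19
mutant            0          0            39       21
  class chi-square: 0.150, df = 1, p = 0.6985
  retrograde run length (n = 585 / 513 runs): medians 3.06 / 2.26 um, Mann-Whitney p = 9.323e-07
  mean retrograde speed (n = 41 / 39 tracks): Mann-Whitney p = 0.1809
  total retrograde distance: Mann-Whitney p = 2.007e-05
```

Reading this: the movement-class mix is indistinguishable between genotypes
(chi-square p = 0.70), but pooled retrograde run lengths are shorter in the
mutant (observed medians 3.06 vs 2.26 µm — the ≥1.5 s run filter inflates
observed medians above the ground-truth 2.52/1.91 µm targets) and total
retrograde distance per lysosome is reduced — the transport phenotype the
generator was configured to produce. Only tracks traced ≥ 60 s with at least
one retrograde run enter the per-track metrics (41 and 39 here).

The numbered scripts under `analysis/` run each stage end to end and write
tables, reports and provenance JSON under `results/`:

```sh
Rscript analysis/01_lysosome_trafficking.R
Rscript analysis/02_microtubule_proteomics.R
Rscript analysis/03_laminar_distribution.R
Rscript analysis/04_qpcr_expression.R
```

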