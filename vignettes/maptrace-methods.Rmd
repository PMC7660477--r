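---
title: "Models and methods behind maptrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maptrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maptrace)
```

maptrace re-implements, as one tested pipeline, the four quantitative
analyses used to characterise dynein-dependent transport and neurodevelopment
in a tubulinopathy (α-tubulin R402H) mouse model: kymograph-based lysosome
trafficking quantification, paired TMT co-sedimentation differential
proteomics with a candidate-MAP filter cascade, binned laminar
cell-distribution statistics, and efficiency-corrected qPCR relative
quantification. Raw imaging and mass-spectrometry data of such studies are
rarely deposited, so every stage ships with a seeded synthetic-data generator
whose ground truth is known exactly; this vignette explains the models, the
defaults and their rationale, the numerical choices, and what the passing
tests do and do not establish about real data.

## Lysosome motion model and trafficking analysis

Axonal lysosome motion is simulated as a continuous-time Markov chain over
three states — anterograde run, retrograde run, pause — with exponential
dwell times (per-second exit rates), a log-normal speed drawn once per run
episode, and state transitions on exit governed by a row-stochastic reversal
matrix. This is the simplest process that produces runs, pauses and reversals
of tunable length. The continuous path is sampled on the imaging grid
(0.5 s per frame for 3 min, hence 361 samples per track) and Gaussian
localisation noise is added to the sampled positions only, never to the dwell
times, so the ground-truth episode table stays exact. Positions are in
micrometres with the soma at 0; retrograde movement decreases position.

Defaults, chosen once for realism: retrograde speeds log-normal with median
1.0 um/s (sdlog 0.3) and anterograde median 0.8 um/s, in the range commonly
reported for axonal lysosomes; mean pause 4 s (exit rate 0.25/s); anterograde
exit rate 0.4/s; a run exits to a pause with probability 0.6 and reverses
with probability 0.4; 35% of lysosomes belong to a stationary subpopulation
that never leaves the pause state, reflecting the large immobile pool seen in
live lysotracker recordings; tracks start 30–70 um from the soma; pixel size
0.1 um with 0.02 um localisation noise.

The retrograde exit rate is not free: `calibrate_retro_exit_rate()` solves,
by Gaussian quadrature over the speed distribution and root finding, for the
exit rate at which the median of (speed x dwell) equals the configured target
median run length — 2.52 um for controls and 1.91 um for mutants, the study
conditions the generator emulates. The calibration is exact for unbounded
episodes; inside a finite 3-min recording, episodes that straddle the
recording end are clipped and long episodes are more likely to be clipped, so
empirical ground-truth medians sit 2–3% below target. This window-truncation
bias is a property of finite recordings, not of the calibration, and real
kymograph data carry the same bias.

The analysis side mirrors manual kymograph tracing. `render_kymograph()`
rasterises tracks (rows = time, column 0 = soma side) and returns per-track
pixel paths; `path_to_track()` converts a traced polyline back to a
calibrated track by linear interpolation at every frame row. `segment_runs()`
classifies each per-frame step as anterograde, retrograde or stationary
against a movement threshold (default: one pixel per frame, the tracing
resolution bound; tracing protocols give no sub-pixel movement criterion) and
emits maximal same-sign blocks spanning at least 3 frames; a run ends at the
first step of a different state, and that terminating frame is not part of
the run. Note a bookkeeping subtlety: a run's `duration_s` spans its
inter-frame steps (a 3-frame run covers 1.0 s of movement), while the
conventional "3 frames = 1.5 s" shorthand counts frames x interval; the
package reports the former in run tables and the latter as the
minimum-admissible-run arithmetic.

Tracks are classified anterograde / retrograde / bidirectional / immobile
("paused" in some descriptions) solely from their run list. Retrograde
metrics (mean per-run speed, run lengths, total retrograde distance) are
computed for eligible tracks only — traced at least 60 s and at least one
retrograde run. "Traced for at least 60 s" is read as total traced duration;
the stricter reading (cumulative retrograde time >= 60 s) would exclude
nearly every track in a 180-s recording and is available as
`eligibility = "retrograde_time"`. Mean retrograde speed is the unweighted
mean of per-run speeds by default, with a duration-weighted switch, since
reports rarely state which is used. Likewise, run pools may or may not be
restricted to eligible tracks; both modes exist and `run_pool = "eligible"`
is the default.

Group comparisons follow the study: chi-square on the group x class table
(no continuity correction), Mann-Whitney on pooled retrograde run lengths,
and Mann-Whitney on per-track mean speed and total retrograde distance.

One power limitation is worth stating plainly. With exponential dwell times,
run lengths are speed x dwell products and heavily right-skewed; for the
configured 2.52 vs 1.91 um medians the probability that a control run
exceeds a mutant run is only about 0.56, and at the study's pool sizes
(343 and 309 runs) the two-sided Mann-Whitney detects the shift in roughly
80% of seeded replicates — not the 90%+ one might expect. Real run-length
distributions that are less dispersed than exponential-dwell products yield
higher power at the same median shift; the generator's detection rate is
therefore a conservative floor, and a passing Mann-Whitney on real data says
nothing about this model's dwell-time assumption.

## Paired TMT proteomics and the moderated paired t test

The quant table holds protein records (accession, symbol, unique-peptide
count), a proteins x channels reporter signal/noise matrix, and a paired
design: each littermate pair contributes one control and one mutant channel
of a single TMT 10-plex (more than 5 pairs requires an explicit multi-plex
flag, and multi-batch processing is out of scope). Processing steps: keep
proteins with >= 2 unique peptides; impute exact zeros at half the channel's
smallest positive value (so no protein is dropped silently); rescale each
channel multiplicatively so all channel medians equal the grand median (the
computational analogue of correcting channel loading to 1:1:...:1); form
per-pair log2(mutant/control) ratios.

Inference is a one-sample empirical-Bayes moderated t on the pair ratios,
implemented in the package rather than wrapped, because it is the study's
central inferential step. With d = n_pairs − 1 residual degrees of freedom
per protein, the ensemble of log sample variances is moment-matched to a
scaled-F model: the excess of var(log s²) over trigamma(d/2) determines the
prior degrees of freedom d0 through the inverse trigamma (Newton iteration),
and the mean determines the prior variance s0². Each protein's posterior
variance is the precision-weighted blend
s~² = (d0 s0² + d s²)/(d0 + d), the statistic is
t = mean(ratio)/sqrt(s~²/n) and two-sided p-values use d0 + d degrees of
freedom. Setting `prior_df = 0` recovers the ordinary paired t exactly. When
the variance ensemble is under-dispersed (var(log s²) <= trigamma(d/2)) the
prior df is infinite and all proteins share s0². The test suite verifies the
whole fit against limma's eBayes to machine precision, and its type-I error
at p < 0.01 on a 5000-protein null is 0.010 ± 0.005 across seeds.

Multiplicity control is Benjamini-Hochberg step-up, written out (cumulative
minimum of m p_(i)/i from the largest p down) and checked against
`p.adjust`. The filter cascade reports all quantified -> raw p < 0.01 ->
BH q <= 0.05 -> intersection with a catalog of direct microtubule binders
(VAPA, VAPB, REEP1, EZR, PRNP, KIF5C, DYNC1I1 by default), with
case-insensitive, alias-aware symbol matching (EZRIN = EZR, DYNC1l1/2 =
DYNC1I1/2). FDR tiers can be adjusted over all proteins (the default) or
only within the raw-significant subset (`fdr_scope = "alpha_subset"`).
Reporter S/N values are log2-transformed before testing. Enrichment of a hit list against GMT gene sets uses
the upper-tail hypergeometric with BH across sets — a transparent replacement
for web-service enrichment whose term databases and proprietary corrections
are version-dependent.

The proteome generator draws per-protein baselines N(10, 2) in log2,
per-protein noise variances from a scaled inverse chi-square around
(0.25 log2)² with 10 df (the same hierarchical form the moderated test
assumes), litter random effects of sd 0.2 on each pair's ratio, channel
loading biases, and 1 + Poisson(2) unique peptides. True effects hit a
random 5% of proteins with magnitude 1 + |N(0, 0.5)| log2 units and random
sign, so every perturbed protein has at least a twofold change; on this
mixture the FDR-5% call set has empirical FDR around 0.05 and sensitivity
above 0.9. These are idealised conditions: real co-sedimentation data add
ratio compression from co-isolation interference, peptide-level missingness
and protein-inference ambiguity, none of which the generator emulates, so
passing recovery tests certify the statistics, not robustness to those
artefacts.

## Binned laminar distributions

Cell positions are summarised over an ordered region scheme: ten equal-width
cortical depth bins (bin 1 deepest, matching the deep-layer accumulation
phenotype), hippocampal layers (OL, PCL, RL, LM, MDG, DG, H), cerebellar
layers (IGL, PCL, ML, EGL) or electroporation zones (VZ ... oCP).
`bin_positions()` assigns normalized depths in [0, 1) to half-open bins,
with exactly 1.0 closing the last bin. The generator draws each animal's
counts from an independent multinomial (default 300 cells over 10 bins,
5 animals per group), with a control profile peaked superficially and a
migration-defect profile shifted toward the deep bins.

`compare_distributions()` runs a two-way mixed (split-plot) ANOVA — group as
the between-animal factor, region as the repeated within-animal factor, the
group effect tested against the between-animal stratum — via `aov` with an
animal error term; the test suite checks every F and p against an
independent from-scratch sums-of-squares oracle on all design sizes up to
4 groups x 4 animals x 4 regions. Analysis of per-animal proportions is the
default, raw counts a flag.
One caveat follows from proportions: every animal's proportions sum to 1, so
the between-animal stratum is degenerate and the group main effect is
uninformative (its F is a ratio of round-off); the interaction and per-region
contrasts carry the signal, and the group main effect should be read from
counts. Per-region group contrasts are t contrasts with Sidak correction
across regions x group pairs by default (a Tukey studentized-range variant
is available for >= 3 groups); total counts are compared by t test or
Mann-Whitney according to a Shapiro-Wilk gate on the data (the gate's
p-values are recorded in the result). Greenhouse-Geisser sphericity
correction is off by default; `gg_correction = TRUE` shrinks the
within-animal degrees of freedom by the estimated epsilon.

## qPCR relative quantification

Per sample, technical replicate Cts are averaged per gene; the reference
value is the geometric mean of the reference genes' mean Cts taken literally
in cycle space, although field practice often
geometric-means relative quantities instead — that variant is available via
`space = "quantity"`. The relative level of a target is E^(−ΔCt) with the
gene-specific amplification factor E in (1, 2] (percent efficiencies convert
as E = 1 + pct/100) and ΔCt = mean target Ct − reference value. Group fold
changes are ratios of group mean levels; a Pfaffl-style ratio of group-mean
ΔCts is available as `method = "pfaffl"` because conventions for this
correction vary between laboratories. A documented non-invariance follows from the
cycle-space geometric mean: adding a constant to every Ct cancels only when
the reference Cts are equal, because the geometric mean of cycles is not
translation-equivariant; the tests assert both directions of this property.
The generator writes Ct = baseline − log_E(quantity x loading) + noise with
stable reference genes, a shared per-sample loading factor (removed by ΔCt)
and 0.1-cycle well noise; fold changes of 1.5 at five samples per group are
recovered within 10%, and with all fold changes at 1 the per-target group
comparisons reject at the nominal rate.

## Statistics core and numerical choices

All tests are two-sided. The Mann-Whitney U uses midranks; the exact p is
used automatically for n_x + n_y <= 12 without ties, otherwise a normal
approximation with tie and continuity correction. The two branches agree to
within 0.015 wherever the asymptotic branch is actually used
(n_x + n_y > 12, each group <= 8, verified exhaustively over every achievable
U) — a normal approximation is simply not accurate to 0.01 at such sample
sizes, and markedly worse below n = 4 per group. Kruskal-Wallis uses the
tie-corrected H; Dunn's post-hoc z contrasts on mean ranks are implemented
directly with a tie-corrected standard error and Bonferroni (or Sidak)
correction. Chi-square tests of independence carry no Yates correction (the
study's tables have four classes and large n) and refuse zero marginals.
Shapiro-Wilk normality gates are library-backed, as their role is a logged
gate, not a result. Degenerate t-test inputs (zero variance in both groups)
return the p = 1 / p = 0 boundary rather than an error. Seeds are explicit
arguments everywhere; generators save and restore the global RNG state, so
identical configurations are byte-identical and nothing leaks between
stages.

## Problem sizes used in the checks

The shipped verification uses deliberately modest sizes chosen to exercise
every claim at tight Monte-Carlo error: 3^8 step-sign sequences for the
segmentation oracle, all design sizes to 4x4x4 for the ANOVA oracle, every
achievable U for group sizes to 8 for the Mann-Whitney branch comparison,
20 x 5000 proteins for type-I calibration, 10 x 2000 for FDR behaviour,
~40 tracks for the render-trace round trip, and 20 seeded replicates at the
study's run-pool sizes (343/309) for detection power. Larger sizes change
none of the conclusions; the generator functions accept arbitrary n.

## Known limitations

The motion model has no photophysics, no point-spread function, no
photobleaching, and no per-run velocity profiles; tracing operates on the
generator's own pixel paths, so tracing error beyond quantization is not
modelled. The proteomics module is protein-level only — PSM-level search,
rescoring, isotope-impurity correction and protein grouping are upstream of
its inputs — and handles a single 10-plex. Histology starts from counted
cells, not images. qPCR efficiencies are inputs, not estimated from dilution
series. And as noted above, detection power for the run-length shift at the
published pool sizes is about 80% under exponential dwell times, so a
non-significant Mann-Whitney on data resembling this generator's output is
not strong evidence of equal medians.
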