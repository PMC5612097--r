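---
title: "Methods: peptide-array substrate discovery and coupled-assay kinetics"
author: "pepscreenr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-array substrate discovery and coupled-assay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreenr)
```

# Overview

`pepscreenr` implements the computational side of a transglutaminase
substrate-discovery campaign on ultra-dense peptide microarrays, together
with the kinetic validation of discovered motifs in a glutamate
dehydrogenase (GLDH)-coupled assay. The pipeline has five parts:

1. **Library design** — enumerate and count combinatorial 5-mer libraries
   under exclusion rules, and design maturation and substitution-scan
   follow-up libraries.
2. **Synthetic data** — simulate array fluorescence tables and
   coupled-assay absorbance traces with the statistical structure the
   analysis assumes, so every downstream stage is testable without any
   instrument data.
3. **Array analysis** — replicate-concordance filtering, ranking,
   cross-enzyme comparison, and positional enrichment.
4. **Kinetics** — lag-aware linear-rate extraction, absorbance-to-turnover
   conversion, Michaelis–Menten fitting, and catalytic constants.
5. **Orchestration** — a configuration-driven `run_pipeline()` with
   deterministic, re-runnable artifacts.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the simulations can
demonstrate.

# Library design

A `library_spec()` describes all peptides of a fixed length over an
alphabet, minus sequences violating local rules. The default design uses
the 18 standard amino acids without cysteine and methionine (both are
problematic in photolithographic synthesis), bans adjacent identical
residues (which also bans every longer homopolymer run), and excludes eight
ordered dimers (HR, RH, HK, KH, RK, KR, HP, PQ) anywhere in the sequence.
These motifs interfere with synthesis chemistry or create
streptavidin-binding artifacts that would contaminate a biotin/streptavidin
readout; the dimer list alone accounts for the removal of streptavidin
binders, and no separate removal list exists.

Because all rules are constraints on adjacent residue pairs, the admitted
sequences are exactly the length-\(L\) walks on a directed graph over the
alphabet whose edge set drops self-loops (adjacent-repeat ban) and the
forbidden dimers. `count_library()` counts these walks by the transfer
matrix method: with \(T_{ab} = 1\) when residue \(b\) may follow \(a\),

\[
N(L) \;=\; \mathbf{1}^\top T^{\,L-1} \mathbf{1},
\]

computed as \(L-1\) matrix–vector products in
\(O(L\,|\Sigma|^2)\). `enumerate_library()` materializes the same set by
exhaustive generation and vectorized rule checks; the two agree exactly (a
property the test suite verifies against a brute-force oracle on randomized
small designs). For the default design both give 1,360,732 peptides out of
\(18^5 = 1{,}889{,}568\) candidates; synthesized in duplicate this yields
2,721,464 array features.

Enumeration order is lexicographic in the order of the alphabet vector
(most-significant position first). The canonical 20-letter order minus C/M
is the default; no biological meaning attaches to the order, but a
deterministic order makes peptide ids stable across runs.

Follow-up designs:

* `design_maturation()` extends an invariant core with every combination of
  `n_flank` residues on both termini:
  \(|\Sigma_f|^{2 n_\text{flank}}\) sequences. A 5-mer core with two
  flanking residues per terminus over all 20 amino acids gives 160,000
  9-mers — the published count, which forces the flank alphabet to re-admit
  Cys and Met; `maturation_spec()` therefore defaults to the full
  20-letter alphabet.
* `design_substitution_scan()` generates all sequences at Hamming distance
  1 (and optionally 2) from a parent: \(L(A-1)\) singles and
  \(\binom{L}{2}(A-1)^2\) doubles. The unmodified parent is excluded by
  default (`include_parent = FALSE`); whether the parent is re-synthesized
  on a real scan array is a synthesis decision, not an analysis one.
* `attach_linkers()` samples the 3-residue Gly/Ser 3:1 synthesis linkers
  position-wise. Linkers are a synthesis detail only: peptide identity for
  every analysis remains the un-linkered core, and no motif statistic ever
  sees linker residues.

# The array signal model

`simulate_array()` draws, independently per feature and replicate,

\[
I \;=\; B \;+\; g\, a(p)\, f(c)\, \varepsilon,
\]

with \(B\) lognormal background (mean 180 fluorescence units, sd 40 —
intensities are positive and right-skewed, and 180 is the published
average background), gain \(g\) (default 1), ground-truth activity
\(a(p)\), enzyme-dose response \(f(c) = \min(c/c_\text{ref}, 1)\) (linear
with saturation; only monotonicity matters downstream), and multiplicative
lognormal noise \(\varepsilon\) with CV 0.15. A fraction of features
(default 2%, within the reported 1–3% range) drawn independently per
replicate receives a surface-imperfection spike: the intensity is
multiplied by a uniform draw from 5–50. Spikes hit single replicates, which
is precisely what makes them removable by the concordance filter.

The ground truth `activity_model()` defaults to consensus-distance form:
each planted motif contributes
\(a_m \cdot \delta^{h}\) (Hamming distance \(h\), decay \(\delta = 0.25\)
per mismatch), and a peptide takes the maximum contribution. Planted motifs
score exactly their stated activity (default around 30,000 fluorescence
units at gain 1, i.e. a strong array hit about 170-fold over background),
far above the 99.9th percentile of the non-planted bulk, so recovery is
well-posed. A position-weight mode is available for graded, additive
specificity models.

`simulate_concentration_pair()` reproduces the two-array Lys-substrate
screen: two simulations identical except for enzyme concentration (0.1
vs 0.01 ng/µl) and seed. `average_concentration_pair()` then filters each
array separately, averages per-array means, and keeps only peptides passing
both filters — matching an analysis whose axes are per-array signals.

What the simulator does *not* emulate: spatial structure (scanner gridding,
local background smoothness, neighbor bleed), synthesis yield differences
between peptides, and any calibrated dose–response of signal on enzyme
concentration or incubation time. Passing recovery tests therefore shows
the analysis is correct *given* the stated noise structure, not that the
noise structure matches any particular instrument.

# Replicate concordance and ranking

Duplicate synthesis gives two on-array copies \(S_1, S_2\) per peptide. The
noise filter excludes peptides with

\[
\left| \frac{S_1 - S_2}{S_1 + S_2} \right| > 0.2,
\]

a strict inequality: a pair sitting exactly at 0.2 is retained. Pairs with
\(S_1 = S_2 = 0\) (undefined statistic) are removed as well. The statistic
is symmetric in the replicates and invariant under joint positive
rescaling, so the filter is unit-agnostic — scanner units never matter.
Every exclusion is logged with its replicate intensities and statistic.

Ranking averages the two copies arithmetically (the only averaging the
source analysis plots), sorts descending, and breaks exact ties
lexicographically so the rank vector is a deterministic permutation.
The default selection size is 22, the number of substrates tagged in a
Gln-screen discovery plot.

Whether the filter runs before or after top-k tagging is not prescribed
anywhere; the pipeline filters first, since excluded features are excluded
"from analysis", and tagging is analysis.

# Cross-enzyme reactivity

`cross_reactivity()` traces enzyme A's top-k substrates into enzyme B's
mean-intensity distribution, reporting for each peptide the percentile

\[
P \;=\; 100 \cdot \frac{\#\{x < m\} + \tfrac12\,\#\{x = m\}}{n},
\]

the midpoint-corrected fraction of B's peptides below it, plus the median
and interquartile range. "Midfield" has no published numeric definition, so
the percentile convention is stated here explicitly: orthogonal enzymes
leave each other's best substrates near the middle of the distribution
(median percentile well below the top tail), while self-comparison pins
them at the top. Top-k peptides absent from B's table (for example,
filtered out on B's array) are reported as missing rather than dropped, so
the denominator of any summary is visible.

`positional_enrichment()` summarizes top-k composition per position as
\(\log_2\) ratios of pseudocount-regularized frequencies against a
background set (pseudocount 0.5 per residue count); the consensus of
per-position maxima recovers a planted motif exactly in simulation.

# The GLDH-coupled assay model

The coupled assay reads transglutaminase activity through ammonia:
deamidation of the Gln substrate releases NH3, which GLDH consumes together
with NADH in the reductive amination of 2-oxoglutarate; A340 tracks NADH.
`simulate_kinetic_trace()` integrates (with `deSolve`, `lsoda`,
`rtol = atol = 1e-9`)

\[
\dot S = -v(S), \qquad
\dot N = v(S) - k N, \qquad
\dot{\mathrm{NADH}} = -k N, \qquad
v(S) = \frac{V_\max S}{K_m + S},
\]

with \(V_\max\) in pmol/s per well converted to µM/s through the 200 µl
well volume, GLDH first-order in ammonia with rate constant \(k\) (default
0.05 s⁻¹; 2-oxoglutarate and NADH are in excess, and the reporter stops if
NADH runs out), and \(A_{340} = \alpha \cdot \mathrm{NADH}\) plus additive
Gaussian noise. Mass balance — NADH consumed equals cumulative ammonia
processed — holds exactly by construction and is asserted in tests.

The transient solution of the ammonia pool gives the lag: \(N\) relaxes to
its steady state \(v/k\) with time constant \(1/k\), after which
\(\dot A_{340} = -\alpha\, v(S)\) — the published lag-then-linear shape.
Halving \(k\) visibly lengthens the fitted lag.

Defaults and their reasoning:

* `nadh0 = 500` µM, `trace_duration = 3600` s — the published assay
  conditions (500 µM NADH, 60 min recording).
* `sample_interval = 15` s — 241 samples per trace, a typical plate-reader
  cadence with shaking between reads.
* `absorbance_per_nadh = 0.003` AU/µM — a path-length-scale instrument
  constant chosen once so that the unit loop closes against the published
  mAU/min→pmol/s conversion: \(1.111 \times 0.003 \times 60000 / 200 =
  0.9999\), i.e. the simulator and the converter agree to 0.01%.
* `noise_sd = 5e-4` AU (0.5 mAU) — realistic absorbance noise for a
  temperature-controlled microplate reader averaging each read.
* `substrate_concs` — eight points from 62.5 to 1000 µM, spanning the
  published 0–1 mM titration range around a Km of order 1 mM.

# Rate extraction and Michaelis–Menten fitting

`extract_linear_rate()` makes the informal notion of "the linear rate after
a short lag" operational: scanning window start points in time order, the
lag ends at the earliest start from which at least one window of ≥10
samples achieves a straight-line fit with \(r^2 \ge 0.995\); among the
windows anchored there, the longest qualifying one is returned. A constant
window counts as perfectly linear with slope zero, so a substrate-free
trace yields rate 0 over the full trace. If no window qualifies the
function fails loudly with the best \(r^2\) seen — a quality error, not a
silent guess. Both thresholds are arguments; 0.995 and 10 samples are
package defaults, since no operational rule is published.

`absorbance_to_turnover()` converts the fitted slope with the empirical
instrument constant: turnover (pmol/s) = |slope (mAU/min)| × 1.111. The
constant comes from an NADH standard curve, so it is a configurable
`assay_design()` field, never re-derived from extinction coefficients.

One bias deserves explanation. At low substrate a one-hour trace consumes
an appreciable fraction of the well (at 62.5 µM with \(V_\max = 37\)
pmol/s, about half), so any finite fit window measures a chord whose slope
approximates the rate at the *mid-window* substrate concentration, not the
nominal starting one. Fitting those rates against nominal concentrations
inflates both parameters substantially. `analyze_kinetics()` therefore
applies a substrate-depletion correction by default: the trace itself
measures consumption (each mAU of A340 decline corresponds to
`conversion_factor × 60` pmol of NADH, hence of substrate, 1:1 through
ammonia), and each rate is paired with the mid-window concentration

\[
S_\text{eff} \;=\; S_0 - \frac{\big(A(0) - \hat A(t_\text{mid})\big)}
{\alpha_\text{design}} ,
\]

computed entirely from the trace and the assay design. With the correction
the simulation round trip recovers \(V_\max\) within 0.5% and \(K_m\)
within 2% at default noise; without it the errors are tens of percent. The
correction can be disabled (`depletion_correction = FALSE`) for pre-reduced
data.

`fit_michaelis_menten()` is Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) of \(v = V_\max S / (K_m + S)\), unweighted (no
variance model is published; standard errors are asymptotic), initialized
at \(V_{\max,0} = \max v\) and \(K_{m,0}\) interpolated as the
concentration at half of \(V_{\max,0}\), with a median fallback when the
half-maximum is not bracketed. Requiring ≥4 distinct nonzero substrate
concentrations keeps the two-parameter hyperbola honestly identifiable.
All-zero rates return a "not detectable" result with no parameters —
the same way an unreactive enzyme–substrate pair is tabulated — rather
than a degenerate fit.

`derive_catalytic_constants()` computes
\(k_\text{cat} = V_\max / n_\text{enzyme}\) with
\(n_\text{enzyme} = c_\text{enzyme} V_\text{well} / M_W\)
(default 5 µg/ml × 200 µl / 26,400 Da = 37.9 pmol for the
*Kutzneria albida* enzyme's active form) and the efficiency
\(k_\text{cat}/K_m\) in M⁻¹s⁻¹ at 3 significant figures — the precision at
which the published efficiency values 1640 and 1440 M⁻¹s⁻¹ reproduce from
their printed \((k_\text{cat}, K_m)\) pairs. The commercial reference
transglutaminase has no published molecular weight, so `enzyme_mw` has no
meaningful default for it and must be supplied; with kcat computed from
Vmax the efficiency follows regardless. The amine-donor substrate is
treated as saturating throughout; no inhibition model (including product
inhibition by ammonium) is implemented.

# Orchestration and reproducibility

`run_pipeline()` drives all stages from a single config (R list or YAML):
unknown keys are rejected before anything runs, a seed is mandatory, and
every stochastic stage derives its stream from it unless the stage sets its
own. Artifacts are plain text (TSV/CSV/JSON, floats at 6 significant digits
in report files), one run-log row per stage with row counts and a hash of
the scientific configuration (the output path is excluded from the hash so
relocating a run does not change its identity). Reruns of the same config
are byte-identical, which the test suite asserts file by file.

The packaged `demo_config()` — a 5,000-peptide sublibrary with two planted
Gln motifs, a disjoint-motif comparison enzyme, and a simulated titration —
exercises design → simulate → filter → rank → mature → compare → fit end to
end in a few seconds.

# Problem sizes used in the tests

The test suite runs enumeration oracles on randomized designs of up to
\(6^5\) candidates, recovery benchmarks on 20,000–50,000-peptide
sublibraries (the 50,000-peptide case over five seeds mirrors a realistic
screen at about 1/27th of the full library, keeping a full recovery sweep
near a minute), and kinetic round trips over the eight-point titration.
These sizes were chosen as the smallest that leave the statistical
questions intact: spike fractions and filter power are per-feature
properties independent of library size, and motif recovery only sharpens as
the library grows because planted signals are fixed while the background
order statistics grow slowly.

# Known limitations

* The dose–response \(f(c)\) is monotone by construction but not calibrated
  to any instrument; conclusions about absolute enzyme concentrations are
  out of scope.
* Replicate backgrounds are drawn independently, which overstates
  background discordance relative to a real array's spatially smooth
  background; the filter's false-exclusion rate in simulation (roughly a
  fifth of clean features at default noise) is therefore pessimistic.
  An occasional planted motif lost to a simulated spike is expected and is
  why recovery is asserted over seed ensembles, not per seed.
* Double spikes hitting both copies of the same peptide concordantly are
  rare but possible; the filter cannot remove them, and they can occupy
  top-k slots without displacing strong planted hits.
* The GLDH reporter is reduced to first-order kinetics in ammonia; the full
  bisubstrate mechanism, NADH absorbance nonlinearity, and path-length
  variation between wells are not modeled.
* Kinetic parameters assume the amine donor is saturating; there is no
  global fit across substrates or enzymes.
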