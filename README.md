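# pepscreenr

Substrate discovery for transglutaminases (and other peptide-modifying
enzymes) on ultra-dense combinatorial peptide microarrays, with kinetic
validation by a GLDH-coupled assay.

Microbial transglutaminases form Gln–Lys isopeptide bonds and are
workhorses for site-specific protein conjugation — but only if the enzyme's
recognition motif is known and specific. One way to find it is to
synthesize millions of short peptides on an array in duplicate, react the
array with the enzyme and a biotinylated co-substrate, and rank peptides by
fluorescence; candidate motifs are then matured on follow-up arrays and
validated in solution by coupled-assay kinetics. `pepscreenr` implements
the computational side of that campaign for people designing such screens
or re-analyzing their outputs: library designers with exact counting,
a simulator with planted ground truth for benchmarking, the
replicate-concordance noise filter, ranking and cross-enzyme comparison,
and Michaelis–Menten fitting with derived catalytic constants.

## The core computations

**Library design.** All peptides of length *L* over an alphabet Σ (default:
18 amino acids, no Cys/Met), minus any sequence with two adjacent identical
residues or containing a forbidden dimer (default HR, RH, HK, KH, RK, KR,
HP, PQ). Since every rule constrains adjacent pairs, the library size is a
transfer-matrix path count, N(L) = **1**ᵀ T^(L−1) **1** with T the allowed
residue-transition matrix — `count_library()` evaluates this in
microseconds and agrees exactly with full enumeration. The default design
has 1,360,732 peptides (2,721,464 features in duplicate synthesis).
Maturation libraries (core ± flanks: |Σ|^(2n) sequences, e.g. 160,000
9-mers from a 5-mer core) and single/double substitution scans
(L(A−1) + C(L,2)(A−1)² variants) cover follow-up rounds.

**Noise filtering.** Duplicate synthesis gives two copies S₁, S₂ per
peptide; features with |(S₁−S₂)/(S₁+S₂)| > 0.2 are excluded (surface
imperfections spike single copies). The statistic is symmetric and
scale-invariant, so scanner units never matter.

**Kinetics.** The coupled assay reads transglutaminase turnover through
ammonia-driven NADH oxidation at 340 nm: after a lag (the ammonia pool
filling to steady state) the absorbance falls linearly. The package
extracts the post-lag linear slope (earliest window with r² ≥ 0.995,
extended as far as linearity holds), converts mAU/min to pmol/s with the
empirical ×1.111 instrument constant, corrects each rate for substrate
already consumed (read off the trace itself), and fits
v = V·S/(Km+S) by Levenberg–Marquardt least squares. Catalytic constants
follow from the assay design: kcat = Vmax/n_enzyme, efficiency kcat/Km in
M⁻¹s⁻¹ at 3 significant figures.

## Worked example

Design the library, simulate a Gln-substrate screen on a 50,000-peptide
sublibrary with two planted motifs, filter, and rank:

```r
library(pepscreenr)

spec <- library_spec()
count_library(spec)
#> [1] 1360732

lib <- enumerate_library(spec)
sub <- sample_sublibrary(lib, 50000, seed = 1, include = c("YRYRQ", "RYRQR"))
model <- activity_model(planted_motifs = c(YRYRQ = 30000, RYRQR = 27000))
tbl  <- simulate_array(sub, model, array_sim_config(seed = 1))
filt <- concordance_filter(tbl)
nrow(attr(filt, "exclusions"))
#> [1] 6669

prof <- rank_peptides(filt, k = 22)
head(prof, 5)
#> # A tibble: 5 × 4
#>   peptide mean_intensity  rank top_k
#>   <chr>            <dbl> <int> <lgl>
#> 1 RYRQR           29068.     1 TRUE
#> 2 YRYRQ           28536.     2 TRUE
#> 3 ITPRA            9657.     3 TRUE
#> 4 DIGYP            8641.     4 TRUE
#> 5 YRYRL            8175.     5 TRUE
```

Both planted motifs surface at ranks 1–2, about 170-fold over the ~180-unit
background; the next entries are background survivors and near-motif
variants (note `YRYRL`, one mismatch from `YRYRQ`).

Validate kinetics on a simulated GLDH-coupled titration (eight substrate
concentrations, 0–1 mM) and recover the parameters:

```r
params <- coupled_assay_params(Vmax_true = 37, Km_true = 847, seed = 1)
traces <- lapply(params$substrate_concs,
                 function(s) simulate_kinetic_trace(params, s))
fit <- analyze_kinetics(traces)
fit
#> <mm_fit>
#>   Vmax = 37.15 pmol/s (se 0.0624)
#>   Km   = 858.9 uM (se 2.33)
#>   kcat = 0.9807 1/s;  kcat/Km = 1140 1/(M s)
```

The true (Vmax, Km) = (37 pmol/s, 847 µM) come back within 0.5% and 1.5%;
kcat here uses the default assay design (5 µg/ml enzyme, 200 µl well,
26.4 kDa). `tidy()`, `glance()`, and `autoplot()` work on the fit;
`plot_replicate_concordance()` and `plot_kinetic_trace()` draw the standard
views of the other result types. `run_pipeline(demo_config())` chains the
whole workflow from one seeded configuration with deterministic artifacts.

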