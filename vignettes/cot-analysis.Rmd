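---
title: "Reassociation kinetics, library coverage, and repeat distribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reassociation kinetics, library coverage, and repeat distribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotkit)
```

# The model

Cot analysis studies genome structure through the kinetics of DNA
reassociation in solution. After denaturation, the rate at which a sequence
class renatures depends on its concentration: abundant (repetitive)
sequences find complementary partners quickly, single-copy sequences slowly.
For a homogeneous class with second-order rate constant $k$
(M$^{-1}$s$^{-1}$), the single-stranded fraction decays as $1/(1 + kC_0t)$,
where $C_0t$ ("Cot", M·s) is the product of initial concentration, time and
a buffer factor. A genome is modeled as a mixture: components $i$ with
genome fractions $f_i$ and rates $k_i$, plus a *foldback* fraction
$f_{fold}$ (hairpin-forming sequences that renature essentially
instantaneously, modeled as a Cot-independent offset) and an
*unreassociated* residue that never renatures over the observed range. The
fraction of total DNA reassociated at Cot value $c$ is

$$y(c) = f_{fold} + \sum_i f_i \frac{k_i c}{1 + k_i c},$$

increasing from $f_{fold}$ at $c = 0$ to $1 - f_{unre}$ as $c \to \infty$.
The package works in fraction-reassociated space; datasets recorded as
fraction single-stranded (the hydroxyapatite convention) are converted with
`as_cot_data(..., single_stranded = TRUE)`.

Derived statistics per component:

* **Observed Cot½** $= 1/k_i$: the Cot at which half the component has
  renatured.
* **Pure Cot½** $= f_i/k_i$: the Cot½ the component would show if studied
  in isolation at the whole-sample concentration.
* **Kinetic complexity** (Mb) $= (f_i/k_i)\,R$: the pure Cot½ scaled by a
  calibration genome's complexity-to-Cot½ ratio $R$. The default standard
  is *E. coli*: complexity $4.639\times10^6$ bp with pure Cot½ 4.57 M·s,
  i.e. $R = 1.0151$ Mb per M·s. The complexity figure is the canonical
  *E. coli* genome length; the Cot½ was calibrated once so that the
  reference mixture's moderately-repetitive kinetic complexity reproduces
  its published value from its own printed $f$ and $k$ — both fields of
  `calibration_standard()` are user-configurable for other reaction
  conditions.
* **Mean repetition frequency (MRF)** $= k_i/k_{SL}$: average genome copy
  number relative to the single/low-copy (SL) component, whose MRF is 1 by
  definition.
* **Two-Cot-decade region (TCDR)**: 80% of a second-order component
  renatures between $0.1\,\mathrm{Cot}_{1/2}$ and $10\,\mathrm{Cot}_{1/2}$;
  in copy-number space, between MRF/10 and 10·MRF.
* **Genome-size-fixed slow rate**: when the 1C size $G$ is known
  independently, $k_{SL} = R/G$ — the algebraic inverse of the kinetic
  complexity relation with copy number 1 over the whole genome.

With three components they are labeled HR/MR/SL (highly repetitive,
moderately repetitive, single/low-copy) by descending rate; other counts
get neutral `C1...Cn` labels.

`taxodium_cot_model()` ships the published three-component mixture for bald
cypress (*Taxodium distichum*, 1C = 9731 Mb). Its printed fractions carry
display rounding and sum with foldback to 0.9967, so the constructor closes
the model by recomputing the unreassociated residue (0.0266 instead of the
displayed 0.0233); the residue enters none of the derived statistics.
`component_table()` applies the conventional display rounding in one place —
MRF to integers, Cot½ to 2 decimals, kinetic complexity to 4 significant
figures, copy ranges from the rounded MRF — so printed columns are mutually
consistent.

# Curve fitting

`fit_cot_curve()` estimates the mixture from observed points by nonlinear
least squares (Levenberg–Marquardt via minpack.lm), minimizing
$\sum_j w_j (y_j - y(c_j))^2$. Choices that matter:

* **Parameterization and bounds.** Rates are optimized as $\log_{10} k$
  within $[10^{-8}, 10^4]$; fractions and foldback within $[0, 1]$ with a
  soft penalty keeping their total at most 1, the remainder becoming the
  unreassociated residue. Residuals are computed in fraction space,
  unweighted by default.
* **Multi-start.** 25 restarts: rates initialized on a log grid spanning
  the reciprocal Cot range of the data (jittered after the first start),
  fractions near-uniform. Best sum of squares wins; exact ties go to the
  lexicographically smaller parameter vector. The whole schedule is a
  deterministic function of one integer seed, so refitting shuffled rows
  or refitting twice gives identical answers.
* **Fixed slow rate.** `fixed_slow_rate` clamps the slowest component
  (free rates are kept at least 0.3 decades above it). This mirrors the
  standard practice of fixing $k_{SL}$ from a flow-cytometric genome size
  when the data do not extend far enough to resolve the slow component —
  see Limitations.
* **Outlier rejection.** Externally studentized residuals using the
  Jacobian-based leverage of the nonlinear fit; the worst point above the
  threshold (default 3.0) is removed, the model refitted, and the loop
  repeats until no point exceeds the threshold or 10% of points have been
  removed. A numerically perfect fit short-circuits the loop.
* **Model selection.** `select_cot_model()` fits 1..`max_components`
  candidates, applies outlier rejection to each, and picks the candidate
  minimizing AICc (BIC available); AICc's small-sample correction matters
  because a 5-component fit spends 11 parameters on typically 40–80
  points. Candidates whose adjacent rates collapse within 0.3 decades are
  excluded from the comparison (two components closer than that are not
  kinetically distinguishable); at least 3 points per free parameter are
  required.

# The synthetic-data generators

All generators are pure functions of their arguments, seed included, and
restore the caller's RNG state.

* `simulate_cot_dataset()` evaluates the forward curve on a log-spaced Cot
  grid (default 60 points over $10^{-3}$–$10^5$ M·s, the span of a typical
  renaturation experiment) and adds i.i.d. Gaussian noise on the fraction
  scale, clipped to $[0,1]$. The default noise SD of 0.01 represents a
  careful hydroxyapatite fractionation series; no published error model
  exists, so the noise is a configurable idealization — real Cot data have
  Cot-dependent, occasionally asymmetric errors that this generator does
  not emulate.
* `simulate_macroarray()` models a hybridization screen: an array of $N$
  clones covering $N\times\mathrm{insert}/\mathrm{genome}$ genome
  equivalents receives `round(copies × coverage)` element copies. With
  `clustering = 0` copies land multinomially with uniform probabilities —
  the null hypothesis of the occupancy test. With `clustering` $> 0$,
  clone propensities are drawn from a symmetric Dirichlet with
  concentration $1/\mathrm{clustering}$, one interpretable dial from
  random to clumped.
* `plant_mites()` builds repeat-dense synthetic reads: i.i.d. background
  nucleotides at GC 0.38 (typical of conifer genomic reads) into which
  elements with the canonical MITE structure are inserted — direct repeat
  (DR), terminal inverted repeat (TIR), internal spacer, reverse
  complement of the TIR, second DR — separated by short spacers (40–120
  bp by default, emulating the element density of repeat-enriched
  Cot-filtered reads). The generator guarantees the truth table is the
  *maximal* structure: the DR's first two bases differ (no periodic
  extension), the outermost DR bases are non-complementary (no outward
  TIR growth), and the internal spacer's terminal bases are
  non-complementary (no inward TIR growth). Without these guards a
  planted element's true boundary would occasionally be ambiguous and the
  truth table mislabeled; they constrain roughly one background
  arrangement in four, leaving composition effectively unchanged.

# The occupancy (urn) test

Whether a repeat is randomly scattered among arrayed clones is tested with
Holst's occupancy asymptotics for the number of empty urns: placing $n$
copies among $N$ clones with per-clone probability $p$, the empty-clone
count has mean $N e^{-np}$ and standard deviation $\sqrt{n^2 N p^2/2}$
(equal to $n/\sqrt{2N}$ at the uniform $p = 1/N$). `deviation_ratio()`
reports the screen's headline statistic — the observed empty count divided
by that SD — *verbatim as historically used*, and alongside it the
conventional z-score $(\mathrm{obs} - \mathrm{mean})/\mathrm{sd}$, which is
the statistically meaningful quantity; `test_random_distribution()` bases
its verdict on the z-score with a deliberately extreme default threshold
of 5. The SD expression was chosen because it exactly reproduces the
published worked example; the closed forms are cross-checked against
multinomial simulation in the test suite (1,000 replicates at $N = 1000$,
$n = 300$, agreement within 3 Monte-Carlo standard errors).

# Library accounting

`library_profile()` + `library_report()` implement the standard BAC library
arithmetic: nuclear clones = total × (1 − false-positive rate − organellar
rate), or a directly determined nuclear count when the upstream screen
provides one (the two can disagree by a few hundred clones when pooled
rates carry display rounding); genome equivalents = clones × insert /
genome (kb/Mb conversion exact); and the Clarke–Carbon probability
$1 - (1 - \mathrm{insert}/\mathrm{genome})^{\mathrm{clones}}$ that a locus
is represented at least once. Display rounding: counts to integers,
fractions to 3 decimals, library coverage to 2 decimals, per-array coverage
to 3 (the third digit is meaningful at 0.2×).

# The MITE scanner

`scan_mites()` finds candidate miniature inverted-repeat transposable
elements with a seed-and-extend strategy: all exact `min_tir`-mer inverted
matches within the allowed element-length window are found through a k-mer
hash; each seed pair fixes the element's outer boundaries, and the TIR is
extended inward while bases keep pairing (up to `max_tir`, spending at most
`max_tir_mismatches`; default exact). The longest identical flanking direct
repeat within `[min_dr, max_dr]` is then required immediately outside the
boundaries (`require_dr = FALSE` relaxes this — whether genuine elements
always retain a detectable target-site duplication is unsettled, and very
short DRs carry little evidence either way). `N` never matches. Default
bounds are the conventional screen for short non-autonomous elements: TIR
8–50 nt, DR 2–30 nt, element 100–1000 nt.

Competing candidates are resolved in one greedy pass, longest TIR first,
ties to the longer (outermost) element, then leftmost. Because inward
extension gives the outermost member of a nested seed family the longest
TIR, this keeps exactly the maximal form of each real element; an
outermost-first rule was tried and rejected because a chance
minimum-threshold candidate (8-nt TIR with a 2-nt DR arises by coincidence
about once per few kb of random DNA) that happens to span a genuine element
would displace it. Coordinates are 1-based inclusive throughout the R API
(the Bioconductor convention); TSV output states this in its header and
GFF3 output is 1-based per the standard. `summarize_mites()` groups
candidates into families by exact TIR sequence identity only — consensus
building and similarity clustering are out of scope.

# Verification strategy and problem sizes

Every stage is tested against fixtures generated by the package itself, at
sizes chosen to run in about a minute in total:

* Kinetics arithmetic against the published bald cypress component table
  (exact, after display rounding).
* Parameter recovery: 20 replicates of 60-point datasets at noise SD 0.01
  simulated from the reference mixture; model selection over 1–4
  candidates with the slow rate fixed from genome size (the published
  procedure) must choose 3 components and recover fractions within ±0.05
  and rates within ±0.15 decades; a noise-free dataset must be recovered
  to $10^{-6}$.
* Occupancy closed forms against 1,000 multinomial replicates at
  $N = 1000$, $n = 300$.
* Scanner: plant-and-recover over 50 read fixtures carrying 1–5 elements
  each (TIR 10–20 nt, DR 2–8 nt, elements 150–400 bp), requiring 100%
  recall and ≥95% precision against exact planted coordinates, plus the
  strand-symmetry invariant (scanning a reverse complement mirrors all
  coordinates) on 50 further fixtures.

Passing these suites shows the implementation is internally consistent and
recovers known truth under the generators' idealizations; it does not show
that real renaturation data meet the Gaussian noise model, nor that real
repeat landscapes resemble i.i.d. background with clean planted elements.

# Limitations

* **Slow-component identifiability.** When the Cot grid ends before the SL
  component fully renatures (e.g. $10^5$ M·s against an SL Cot½ near
  $10^4$), a free fit still selects the right component count and accurate
  fractions, but $k_{SL}$ is weakly determined (errors up to ~0.3 decades
  at noise SD 0.01). This is intrinsic to the data window, not the
  optimizer, and is the reason the genome-size-fixed slow rate exists;
  with it, all rates recover within ±0.05 decades. A consequence: a
  fixed-slow-rate curve cannot itself estimate genome size.
* **Scanner specificity at minimum thresholds.** An 8-nt exact TIR with a
  2-nt DR is weak evidence; in long, repeat-sparse random sequence, chance
  candidates at these thresholds are statistically expected at roughly one
  per few kb. Statistical scoring and family clustering, which production
  MITE finders add on top, are out of scope here.
* **No buffer-factor or thermal corrections.** Cot inputs are assumed
  already expressed in equivalent Cot units; melting-curve analysis and
  hyperchromicity corrections are out of scope.
* **The urn test's ratio statistic** (observed/SD) is reported for
  fidelity to historical usage but is not a test statistic in the usual
  sense; verdicts use the z-score.
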