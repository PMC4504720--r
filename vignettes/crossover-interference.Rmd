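---
title: "Measuring crossover interference from tetrads, chiasmata, and axis signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover interference from tetrads, chiasmata, and axis signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetracross)
```

## The measurement problem

During meiosis each pair of homologous chromosomes (a bivalent of four
chromatids) receives one or more crossovers (COs). COs are not placed
independently: an event in one region suppresses nearby events — crossover
interference. `tetracross` quantifies interference and recombination rates
from three complementary observations:

* **FTL pollen tetrads.** In a `qrt` background the four pollen grains of a
  meiosis stay attached, and linked fluorophore transgenes (in coupling on
  one homolog) let each grain's genotype across 2–3 markers be read under a
  microscope. The atomic datum is a tetrad: 4 grains × up to 3
  presence/absence calls.
* **Chiasma counts.** At metaphase I the number of chiasmata per cell is
  counted; a bivalent with no chiasma appears as a pair of univalents.
* **Axis-protein intensities.** Mean grey-scale intensities of axis-protein
  immunosignal on synapsed vs unsynapsed chromosome regions, calibrated by
  fluorescent microspheres co-imaged on each slide.

## Tetrad estimators

For one marked interval a tetrad has 0, 2, or 4 recombinant grains: parental
ditype (PD), tetratype (TT), non-parental ditype (NPD). The Perkins
estimator converts counts to map distance,

$$\hat X = 100\,\frac{TT/2 + 3\,NPD}{n}\ \text{cM},$$

whose NPD term corrects for 4-strand double COs. We report a delta-method
standard error from the multinomial distribution of (PD, TT, NPD): with the
per-tetrad contribution $w \in \{0, 1/2, 3\}$,
$SE = 100\sqrt{(\overline{w^2}-\bar w^2)/n}$. `compare_map_distances()`
contrasts two independent estimates with a Z statistic on their difference.

For two adjacent intervals, the joint (state 1, state 2) classification has
nine cells; the TT/TT cell is further split by the number of grains
recombinant in both intervals (2, 1, 0 — the two-, three-, and four-strand
double COs), giving 11 distinguishable classes labelled A–K
(`tetrad_class_table()`). Some published charts show a 12th group; any
pattern outside this enumeration is reported as `OTHER` rather than forced
into a letter. All statistics depend only on joint states, never on labels.

Two interference statistics are computed from the joint tally:

* **Interference ratio (IR)**: Perkins distance of the test interval among
  tetrads with a CO (TT or NPD) in the adjacent interval, divided by the
  distance among tetrads PD there. Independence gives IR = 1; complete
  interference gives 0. The published description of this method reports a
  Z-score without a formula; we define
  $Z = (d_{without} - d_{with}) / \sqrt{SE_{with}^2 + SE_{without}^2}$
  and validate it by null calibration on simulations rather than claiming
  agreement with any particular software implementation.
* **Coefficient of coincidence (CoC)**: observed double-CO frequency over
  the product of marginal CO frequencies. The literature is ambiguous about
  whether "frequency" is tetrad-level or gamete-level; the default is
  tetrad-level ($f_i$ = fraction of tetrads non-PD in interval $i$, observed
  = fraction non-PD in both), with a gamete-level variant
  (`definition = "gamete"`: $f_i = (TT_i/2 + NPD_i)/n$, observed = fraction
  of grains recombinant in both, computable from the TT/TT overlap
  subtypes). Results state which definition was used.

**Scoring errors.** A grain inconsistent with balanced segregation (1 or 3
recombinant grains in an interval) makes the tetrad unclassifiable; we
exclude it and log the reason rather than guessing, matching visual-scoring
practice. Tallies report excluded counts so denominators stay auditable.

## Chiasma statistics

Without crossover control, per-cell chiasma counts should be Poisson.
`poisson_gof()` fits the sample mean and compares observed counts with the
Poisson expectation by chi-squared:

* `pooled` (default): adjacent count categories merged until every expected
  count is ≥ 5, df = k − 2 (one df for the estimated mean). This is the
  statistically conventional test and the one used in all calibration
  claims.
* `paper`: twelve fixed categories (0–10, ≥ 11) with df = 11, provided for
  comparability with published chi-squared values quoted at 11 df (that
  convention does not subtract a df for the estimated mean).
* `bootstrap`: parametric bootstrap of the pooled statistic (default
  B = 10,000, seeded), for small samples where the chi-squared reference is
  doubtful.

`poisson_range_proportion(mean, lo, hi)` gives the closed-form probability a
Poisson count falls in a window — e.g. 42.8% of cells in 6–8 at mean 6.9 —
against which an observed percent-in-window (from `summarize_chiasma()`)
reveals over-concentration around the mean, the population-level signature
of interference plus the obligate CO.

**Univalent frequency** is not defined uniformly in the literature. Default:
univalent *pairs* per bivalent opportunity, $(\sum u_i/2)/(5 n)$, with five
bivalents per cell; the alternative (percent of cells with ≥ 1 univalent) is
available via `univalent_def = "per_cell"`. Genotype comparisons of focus or
chiasma counts use `rank_test_counts()`: an unpaired Wilcoxon rank-sum by
default — genotype samples are unpaired, even though methods sections often
write "signed-rank" — with the paired signed-rank behind `paired = TRUE`;
output states which ran. Fully tied input returns p = 1 with a warning.

## Intensity normalization

`normalize_intensity()` divides ROI means by the co-imaged microsphere mean,
exactly cancelling any multiplicative gain common to both (illumination,
exposure). `paired_reduction()` reports
$100(1 - \bar s/\bar u)$ on normalized values plus a two-tailed paired
t-test. The mean of per-cell ratios is also reported: the two differ when
intensities vary across cells, and published analyses rarely state which was
used, so both appear in the output. No background subtraction is modelled
(none is described for the measurement protocol this emulates). Degenerate
zero-variance differences short-circuit to t = 0, p = 1 (identical pairs)
rather than erroring.

## The meiosis simulator

The generator exists so every estimator can be validated by parameter
recovery; it is a counting-process model, not a mechanical one.

* **Interference pathway**: a *stationary* gamma renewal process on genetic
  distance along the bivalent. Inter-event gaps are Gamma(shape $\nu$, mean
  $1/\text{rate}$); $\nu = 1$ is Poisson (no interference), larger $\nu$
  spaces events more evenly. Stationarity matters: the first event is drawn
  from the equilibrium forward-recurrence distribution (a uniform fraction
  of a length-biased gap), so event-count laws do not depend on window
  placement and marker spans can be simulated directly.
* **Two pathways**: the interfering process carries fraction
  $1 - p_2$ of the total rate and an independent homogeneous Poisson process
  carries $p_2$ (default `class2_fraction = 0.15`, reflecting the ~85% of
  Arabidopsis COs that show interference). Total rate is fixed at 2 events
  per Morgan on the bivalent — the classical identity between map length
  and bivalent CO count — so map distances are preserved whatever the
  mixture.
* **Chromatids**: each event picks one of the four non-sister pairings
  uniformly (no chromatid interference — the conventional assumption).
* **Tetrads**: grains are read off the chiasma diagram by strand-following:
  a gamete path switches lines at an event iff the event involves the line
  it currently occupies. This guarantees balanced segregation (each marker
  in exactly 2 of 4 grains) and reproduces the classical 4:8:4
  two-:three-:four-strand ratio over the 16 double-CO pairings — both are
  tested exhaustively against an independent permutation-composition
  enumeration. (A simpler "flip parity per event involving the chromatid"
  rule is *not* equivalent: it breaks segregation balance for three-strand
  doubles.)
* **Chiasma samples**: five bivalents with genetic lengths defaulting to
  (95, 75, 60, 60, 55) cM — 345 cM total, chosen so the unconditioned
  expected chiasma count is $2 \times 3.45 = 6.9$ per cell, a realistic
  mutant-scale mean; the obligate CO (each bivalent resampled until ≥ 1
  event, the default for chiasma simulation) raises the realized mean to
  ~9.2, a realistic wild-type-scale value. Rejection sampling distorts the
  marginal rate upward; this is intentional and documented. Without the
  obligate CO, a crossover-free bivalent contributes one univalent pair.
* **Intensities**: per-cell log-normal gain shared by ROI and beads (so
  calibration cancels it exactly), additive Gaussian noise (default SD 0.1)
  on the normalized scale, truncated at zero because grey-scale values are
  non-negative.

All randomness flows through R's RNG, seeded once per generator call via the
config; identical config + seed gives byte-identical tables.

**What the simulator does not emulate**: mechanical beam-film stress
dynamics, DSB-level intermediates, synaptonemal-complex polymerization,
chromatid interference, viability selection against unbalanced spores
(the viability filter hook exists but simulated grains are always balanced),
or scoring noise other than what the ambiguous-tetrad path exercises.
Passing recovery tests therefore show the estimators are correct for a
renewal-type interference process — not that real data satisfy that model.

## Validation conditions and numerical choices

The test suite and `scripts/acceptance.R` use these problem sizes, chosen to
mirror a realistic FTL study while keeping runs to a couple of minutes:
intervals of 6.1 and 5.5 cM at n = 5,000 tetrads (recovery within 3 SE in
≥ 95% of 100 replicates); 10 cM adjacent intervals at n = 20,000 for IR/CoC
null calibration ($\nu = 1$, both within [0.9, 1.1]) and monotonicity
($\nu = 10$ below the $\nu = 1$ value in 20/20 paired replicates); GOF
type-I error on Poisson(6.9), n = 50, 1,000 replicates (within
[0.02, 0.09] at $\alpha = 0.05$) and power > 0.8 on obligate-CO $\nu = 10$
samples; intensity recovery at a true 67% reduction, n = 23 pairs, 500
replicates (mean within 67 ± 3, p < 0.001 in > 95%), with the 0% reduction,
n = 22 null calibrated at $\alpha$.

Numerical conventions: map distances are printed to 1 decimal (full
precision kept internally); chi-squared pooling walks categories upward,
folding a deficient final bin into its neighbour; IR is undefined (error
with diagnostic counts) when a conditioning subset is empty or the
without-CO distance is zero; CoC errors when a marginal CO frequency is
zero; the observable-pattern enumeration treats any three-colour pattern
outside the 11 canonical classes as `OTHER`.

## Known limitations

* Markers must be scored in coupling; repulsion-phase tetrad analysis is out
  of scope.
* The interference shape $\nu$ is a simulator input, not an estimated
  parameter; the package does not fit interference models to data.
* IR/CoC operate on exactly two adjacent intervals; multi-interval joint
  mapping is not implemented.
* The `paper`-mode GOF replicates a fixed-df convention for comparability
  and should not be preferred to the pooled mode for inference.
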