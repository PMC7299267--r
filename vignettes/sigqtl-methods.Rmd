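---
title: "Models and methods: photothermal phenology, synchrony indices, and RIL QTL scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: photothermal phenology, synchrony indices, and RIL QTL scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigqtl)
```

## Scope

`sigqtl` implements three connected analyses for staggered-cohort
(sequential-seeding) phenology experiments in annual plants: photothermal
accounting, a variance-ratio synchrony index, and a single- and two-locus
QTL genome scan for biparental recombinant inbred lines (RILs). A
synthetic-data module generates both experimental designs with known truth.
This vignette records the models, the tunable parameters, and the design
choices made where the methods literature leaves the design open.

## Photothermal units

The forcing a plant perceives on day $i$ is modelled as

$$\mathrm{PTU}_i \;=\; \lambda_i \,(\mu_{Li} - \mu_b)\,
  \mathbf{1}[\mu_{Li} > \mu_b],$$

with $\mu_{Li}$ the mean temperature during daylight hours (°C),
$\lambda_i$ the photoperiod as a fraction of 24 h, and $\mu_b$ the base
temperature below which development is assumed to stop. The default
$\mu_b = 3$ °C is the optimised base temperature reported for modelling the
developmental rate of *Arabidopsis thaliana* (Col-0); it is a `ptu_config()`
argument, not a constant. The inclusion rule is a *strict* inequality: a
day at exactly the base temperature contributes nothing.

**Endpoint convention.** Accumulation over a developmental interval sums
daily contributions over $[\mathrm{start}, \mathrm{end})$: the start day
counts, the event day does not. The convention is not dictated by the
summation formula itself (the equation's index bounds are ambiguous about
endpoint inclusion), but half-open intervals are the only choice under
which vegetative PTU (germination → flowering initiation) and flowering
PTU (initiation → termination) add up exactly to the germination →
termination total, a property the analysis of period lengths implicitly
relies on. A `"closed"` convention is available as a config switch for
sensitivity checks.

**Logger aggregation.** Sub-daily temperature records are averaged,
unweighted, over readings falling in $[\mathrm{sunrise}, \mathrm{sunset})$;
the photoperiod is sunset − sunrise. A day with no daylight reading becomes
a flagged gap. Gaps inside an accumulation interval are a hard error unless
gap filling is explicitly enabled (`ptu_config(gap_fill = TRUE)`), which
linearly interpolates runs up to `max_gap` days and logs the fill. Silent
interpolation is deliberately impossible.

## The SIg synchronization index

For an event $e$ observed in $k$ cohorts sown at staggered dates,

$$\mathrm{SIg}(e) = \log_2
  \frac{\operatorname{Var}(\bar g_1, \dots, \bar g_k)}
       {\operatorname{Var}(\bar e_1, \dots, \bar e_k)},$$

where $\bar g_c$ and $\bar e_c$ are the cohort means of germination day and
event day. Positive values mean the event is buffered against the
germination stagger (SIg = 1 and 2: variance halved and quartered);
negative values mean amplification (−1 and −2: doubled and quadrupled).

Choices worth recording:

* **Variance estimator.** Sample variance ($n-1$) on both sides. The
  estimator choice cancels in the ratio because the implementation requires
  the same cohort set in numerator and denominator.
* **Cohort means, not plants.** Both variances are across *cohort means*;
  for the canonical design the germination means are just the seeding
  offsets $\{0, 7, 14, 21, 28\}$ days (sowing is controlled, so germination
  carries no within-cohort noise).
* **Degenerate variances.** Zero event variance returns $+\infty$ with an
  `exact` flag rather than a capped value — capping would corrupt the
  ordering of the statistic. Zero germination variance (no stagger) makes
  the index meaningless and is classified `undefined`.
* **Missing-data policy.** A cohort contributes to an event only if at
  least 50 % of its plants have the event recorded (configurable
  `min_prop`), so a mean is never driven by one survivor. Classification is
  by sign only; the "strong synchrony" annotation at $|SIg| > 4$ is a
  reporting band, also configurable.

## The synthetic cohort world

`sse_config()` states the simulated world once; its defaults are the
experimental design itself where the design is stated — 5 cohorts,
7-day seeding interval, 8 replicates per cohort, two regimes 3 °C apart —
and a single set of field-plausible values where it is not:

* **Environment.** Daylight temperature $20 - 0.14\,t$ °C (a late-autumn
  decline crossing the base temperature around day 120), day-to-day
  Gaussian weather jitter (SD 0.5 °C) *shared* between regimes so the
  configured offset holds exactly every day, and a seasonal photoperiod
  cosine (mean 12 h, amplitude 2.2 h, minimum near day 19, the December
  solstice for a December-2 first sowing).
* **Flowering rule.** A plant initiates flowering the first day its
  accumulated PTU reaches 200 °C·daylight-days, and bolts at a 40-unit
  lead below that threshold. Under the declining environment this makes
  cohort means of initiation spread ≈ 10 days apart — between-cohort
  variance 2–3× the germination stagger, the reported desynchrony range.
* **Seasonal termination.** Flowering termination and whole-plant
  senescence are fixed calendar days per regime (colder: 115/130; warmer:
  105/120 — the warmer house finishes earlier), which is the
  seasonal-cue hypothesis in its purest form.
* **Event noise.** Independent Gaussian day-jitter per post-germination
  event, SD 1.5 days (the noise magnitude is not stated anywhere; 1.5 days
  is a realistic daily-scoring error), rounded to whole days and re-drawn
  (up to 100 times, then sorted) to preserve the life-cycle ordering
  $g \le \mathrm{bolting} \le fi \le ft \le \mathrm{senescence}$.

What the generator does *not* emulate: accession differences, soil or
watering variation, spatial greenhouse effects, plant-to-plant ethylene
signalling, or mortality. A green end-to-end test therefore establishes
that the pipeline recovers the stated rules from data generated under
them — not that real plants follow those rules.

Dates are integer day offsets from the first sowing throughout the
computational core; ISO-8601 appears only at the I/O boundary, where the
reference date is logged.

## RIL simulation

Genotypes follow a two-state Markov chain along each chromosome: a uniform
start allele and a switch probability between adjacent markers equal to the
Haldane fraction $r = (1 - e^{-2d/100})/2$ of their map distance. Published
RIL maps already embed the map expansion of the selfing generations, so map
distances are consumed as given — the simulator deliberately applies no
additional expansion, matching how the scan itself consumes the map.

Phenotype replicates are
$\mu + \sum_q a_q x_q + \sum_{(q,q')} w\,(2x_q-1)(2x_{q'}-1) + \varepsilon$
with dosage $x \in \{0,1\}$, so an additive effect $a$ is the full
B-versus-A difference and an epistatic term has no marginal effect at
allele frequency ½. `qtl_effect_for_share()` inverts the single-QTL
variance-share relation
$R^2 = a^2/4 \,/\, (a^2/4 + \sigma^2/m)$ for $m$ replicates per line; with
several QTL segregating the realised shares are approximate.

## The QTL scan

**Genotype probabilities.** Markers plus pseudomarkers at most `step` cM
apart (default 2 cM) form the evaluation grid; a forward–backward pass over
the two-state chain gives $P(A), P(B)$ per line and position. The
genotyping error rate defaults to 0 (probabilities collapse at typed
markers) and is configurable for robustness checks. A line untyped on an
entire chromosome gets the flat posterior and a warning.

**Haley–Knott regression.** At each position the phenotype (line means) is
regressed on the expected dosage $P(B)$, giving
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. This is the
regression approximation to interval mapping; full EM interval mapping is
intentionally out of scope (the two are near-identical for complete RIL
data, and the regression form is what the rest of the stack — permutations,
CIM, pair scan — builds on).

**Composite interval mapping.** Marker covariates are chosen by forward
stepwise selection (largest RSS reduction first, partial-*F* entry test at
0.05, ties broken by genome order, at most `n_covariates`, default 3), and
any covariate within `window` cM of the tested position is excluded there.
The canonical window named for this analysis type is 2 cM; since a window
that small barely differs from exclusion-at-the-position, both the window
and the grid step are independent config values rather than one shared
constant.

**Permutation thresholds.** Phenotype labels are shuffled against the
(fixed) genotypes — RILs have no family structure that would demand
stratified shuffling — and the genome-wide maximum LOD of each permuted
scan is recorded; thresholds are the empirical $1-\alpha$ quantiles at
$\alpha = 0.05$ (significant) and $0.63$ (suggestive). The canonical
permutation count is 10 000; tests and the example pipeline use 1 000,
which places the 0.05 quantile within a few hundredths of a LOD unit.

**Credible intervals.** The positional posterior on a chromosome is
$10^{\mathrm{LOD}}$ normalised over the grid (uniform prior). The interval
grows greedily from the peak towards the neighbouring grid point with the
larger posterior until it holds 95 % mass — the smallest contiguous span
containing the peak, by construction. This interval type is known to
undercover slightly at realistic sample sizes; the package's own
calibration test tolerates coverage down to 88 %.

**Peaks and variance decomposition.** One peak per chromosome at the LOD
maximum (leftmost position on ties, deterministically); single-locus
$R^2 = 100(1 - 10^{-2\mathrm{LOD}/n})$; the multi-QTL fit reports drop-one
$R^2$ per term and the total as the heritability estimate, rejecting
numerically collinear peaks by name.

**Two-locus scan.** For every pair on a thinned grid (default 10 cM,
same-chromosome pairs closer than twice the step skipped),
$\mathrm{LOD}_{\mathrm{full}}$ (two dosages + product) and
$\mathrm{LOD}_{\mathrm{add}}$ (two dosages) are computed against the null;
their difference is the epistasis LOD. Nesting guarantees
$\mathrm{LOD}_{\mathrm{int}} \ge 0$ up to numerical tolerance.

## Numerical notes

* LOD via the correlation identity
  $-(n/2)\log_{10}(1-r^2)$ on the fast (covariate-free) path; $r^2$ is
  clipped below 1 to keep LOD finite. The covariate path uses QR
  least-squares; both agree to $10^{-8}$ at typed markers with the plain
  `lm()` oracle.
* Monomorphic dosage columns get LOD 0 rather than NaN.
* Permutation maxima are processed in batches of 250 to bound memory.
* All stochastic operations take explicit integer seeds; identical
  config + seed is bit-identical everywhere, which the tests assert.

## Known limitations

* The phenology engine is a daily-resolution threshold model: no cardinal
  temperature response curves, no chilling/vernalization accounting, no
  hourly thermal time. The accessions this design targets are
  early-flowering precisely because their vernalization requirement is
  weak.
* The scan supports selfed biparental RILs only — two genotype states, no
  dominance, no X-chromosome special-casing, no outbred designs.
* Stepwise covariate selection is greedy; with closely linked QTL of
  opposite sign it can shadow true loci, which is a property of CIM itself
  rather than of this implementation.
* The SIg index compares variances of cohort means only; it does not model
  within-cohort correlation structure, and a mixed-effects decomposition is
  out of scope.
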