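# sigqtl

Phenological synchrony indices and QTL mapping for sequential-seeding
experiments.

## The problem

Annual plants that germinate weeks apart often *senesce together*: the end
of flowering and whole-plant death track the season, not the calendar age
of the plant, while bolting and the start of flowering drift apart because
each cohort has to collect the same amount of photothermal "forcing" under
a declining autumn environment. `sigqtl` packages the quantitative toolkit
for studying this phenomenon in staggered-cohort (sequential-seeding)
experiments and for dissecting its genetic basis in a biparental
recombinant-inbred-line (RIL) population:

1. **Photothermal units (PTU).** Daily forcing is
   `PTU_i = lambda_i * (mu_Li - mu_b)` where `mu_Li` is the mean daylight
   temperature of day *i*, `lambda_i` the photoperiod as a fraction of
   24 h, and `mu_b` the base temperature (3 °C by default). Days with
   `mu_Li <= mu_b` contribute nothing. Accumulation over the vegetative
   (germination → flowering initiation) or flowering (initiation →
   termination) interval uses a half-open convention, so the two periods
   add exactly to the whole-life total.

2. **The SIg synchronization index.**
   `SIg = log2[ Var(cohort means of germination day) / Var(cohort means of event day) ]`.
   `SIg = 1, 2` mean the event's between-cohort variance is halved or
   quartered relative to the germination stagger (synchrony); `SIg = -1,
   -2` mean doubled or quadrupled (desynchrony).

3. **A from-scratch QTL engine** for two-allele RILs: conditional genotype
   probabilities on a pseudomarker grid (two-state hidden Markov chain,
   Haldane map function), Haley–Knott regression LOD profiles
   (`LOD = (n/2) log10(RSS_0/RSS_1)`), composite interval mapping with
   stepwise marker covariates and an exclusion window, genome-wide
   significance (α = 0.05) and suggestive (α = 0.63) thresholds by
   phenotype permutation, 95 % Bayesian credible intervals (posterior ∝
   `10^LOD`), multi-QTL drop-one variance decomposition, and a two-locus
   scan separating additive (`LOD_add`) from epistatic
   (`LOD_int = LOD_full − LOD_add`) signal.

4. **A synthetic-data module** that generates both designs with known
   truth — staggered cohorts under a PTU-threshold flowering rule and
   seasonal senescence dates, and RIL genotype/phenotype sets with
   configured additive and epistatic architectures — so every stage is
   testable without any external download.

## Worked example

The `analysis/` directory holds the numbered pipeline. Stage 1 simulates
the default stated world (5 cohorts × 7-day offsets × 8 replicates × 2
regimes 3 °C apart); stage 2 computes the synchrony statistics:

```sh
Rscript analysis/01_simulate_sse.R
Rscript analysis/02_synchrony_ptu.R
```

```
SIg per event and regime (variance of cohort means, log2 ratio):
 regime          event        sig classification
 colder        bolting -0.9710790 desynchronized
 colder flowering_init -1.3003628 desynchronized
 colder flowering_term  8.8073549   synchronized
 colder     senescence  7.4068170   synchronized
 ...
vegetative PTU by cohort (constant despite longer vegetative periods):
  colder: 200.2, 202.6, 202.4, 200, 202.8  (CV 0.70%)
  colder: r(vegetative, flowering period) = -0.996 (***)
```

Bolting and flowering initiation desynchronize (between-cohort variance
about 2–2.5× the germination stagger, `SIg < 0`) while termination and
senescence synchronize sharply (`SIg > 7`: variance shrunk by more than
two orders of magnitude). Every cohort accumulates the same ~200
°C·daylight-days before flowering even though later cohorts need up to 45
more calendar days, and the vegetative and flowering periods are almost
perfectly anti-correlated — the signature of plants adjusting their
flowering phase to a fixed seasonal end date.

Stages 3–5 simulate the RIL population (105 lines, 144 markers) and scan
three traits:

```sh
Rscript analysis/03_simulate_ril.R
Rscript analysis/04_qtl_scan.R
Rscript analysis/05_scan_two.R
```

```
flowering_init: covariates {M1.02, M5.15, M2.23}; thresholds LOD 2.63 (P<0.05) / 1.22 (P<0.63)
 chr      pos      lod nearest_marker     ci_lo    ci_hi        r2        tier
   1  4.74750 8.974336          M1.02  4.747500  7.83000 32.537835 significant
   5 62.23667 2.458037          M5.15  1.773333 65.30667 10.219865  suggestive
  multi-QTL model: total R^2 = 42.94% (heritability estimate)
```

The planted major chromosome-1 locus is recovered with a tight credible
interval; the weaker loci surface as suggestive peaks; the multi-QTL fit
returns the summed heritability. The pair scan separates the additive
interactions of the flowering loci (`lod_int ≈ 0.1`) from a constructed
chromosome-1 × chromosome-4 epistatic trait (`LOD_int = 21.6` at the
planted pair).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, with the installed package, the analytic calibration points of
the SIg index — the values returned when the between-cohort event variance
is exactly one half, one quarter, twice, and four times the germination
variance — building the cohort means from the experiment's 7-day seeding
offsets and evaluating the index at run time.
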