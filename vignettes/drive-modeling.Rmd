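---
title: "Modeling sex-chromosome-linked CRISPR drive systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sex-chromosome-linked CRISPR drive systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

`drivesim` simulates the population dynamics of CRISPR gene drive systems in
a small mosquito metapopulation and analyzes the Mendelian-cross statistics
that characterize sex-linked Cas9 lines in the laboratory. This vignette is
the package's own account of the model: what is assumed, which parameters
matter, what the synthetic scenarios emulate (and what they do not), and
where genuinely open design choices were settled.

## Inheritance cubes

All drive genetics are encoded in an *inheritance cube*: a dense tensor
$\tau[m, f, o]$ giving the probability that a mother of genotype $m$ and a
father of genotype $f$ produce an offspring of genotype $o$ (offspring
genotype includes sex). Cubes are built from explicit gamete models, never
written down by hand:

1. **Germline modification.** In individuals satisfying the drive's activity
   condition, each wild-type target allele independently takes one of four
   fates per germline passage: conversion to the drive allele with
   probability $c h$ (cleavage $\times$ homology-directed repair), in-frame
   resistance R with probability $\rho\,\phi$, out-of-frame resistance B with
   probability $\rho\,(1-\phi)$, or restoration to wild type with the
   remaining probability. A split drive requires at least one Cas9 allele
   *and* one gRNA allele in the same individual; an autonomous homing
   construct requires only itself plus a wild-type homolog.
2. **Segregation.** Unlinked loci segregate independently; X- and Y-linked
   alleles travel with their chromosome, and offspring sex is decided by the
   sperm (X- vs Y-bearing). Every tensor row sums to 1 within $10^{-12}$, and
   Y-linked alleles can reach only male offspring of carrier fathers — both
   are validated by `validate_cube()` and enforced in the test suite against
   a brute-force enumeration oracle.
3. **X-shredding.** In shredder-carrying males, each shred-susceptible
   X-bearing gamete is destroyed with probability $e$ after a possible
   germline conversion to the resistant state Xr (rate $\rho_x$). Two
   fertility couplings are offered (see Design choices).
4. **Maternal deposition.** With probability $d$ per wild-type target copy,
   zygotes of Cas9+gRNA mothers suffer deposited-nuclease cleavage repaired
   by end-joining only (no homing in the soma), implemented as a
   genotype-to-genotype transition matrix applied to the affected cube rows.

Six architectures are bundled: split drives with Y-linked, X-linked and
autosomal Cas9 (autosomal gRNA/effector in all three), Y-linked and autosomal
X-shredders, and an autosomal homing drive inserted in a female-fertility
gene (females with both alleles in {H, B} are infertile; R rescues).

## Life cycle and demography

The simulator is a daily-timestep, stage-structured model with overlapping
generations: egg, larva and pupa stages are fixed-duration cohort queues (one
slot per day; fractional durations round to the nearest day), adults are
unstructured. Each day, in order: oviposition, juvenile survival and queue
advance, adult survival, eclosion and mating, releases, migration. Females
mate once at eclosion, keep the mate's genotype for life, and a female who
finds no males waits unmated and retries daily.

Larval survival carries the density dependence
$\left(\alpha/(\alpha+L)\right)^{1/T_L}$ per day on top of a
density-independent rate. In stochastic mode survival is binomial, eggs per
mated female are Poisson (fecundity $\beta$ scaled by genotype and by the
cross's fecundity scaling), offspring genotypes are multinomial over the cube
row, and mate choice is multinomial over competitiveness-weighted male
frequencies. The Poisson–multinomial compound is realized as independent
Poisson draws per offspring genotype (exact, and one vectorized draw per
day). Deterministic mode replaces every draw by its expectation.

### Parameters, units, defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| fecundity $\beta$ | eggs/female/day | 32 | standard malaria-vector value for this model class |
| $T_E, T_L, T_P$ | days | 1, 14, 1 | idem |
| $\mu_{adult}$ | 1/day | 0.123 | idem (mean adult lifespan about 8 d) |
| $r_m$ | per day | 1.096 | low-density population growth rate; sets juvenile mortality |
| $N_{eq}$ | adults | 10,000 | scenario equilibrium size per patch |
| migration $m$ | per adult per generation | 0.01 | scenario value; daily rate $m/T_{gen}$ |

Two derivations replace free parameters:

* **Juvenile mortality from $r_m$.** The lifetime female offspring of a
  female at low density equals $r_m^{T_{gen}}$ with
  $T_{gen} = T_E + T_L + T_P + 1/\mu_{adult}$; solving
  $(\beta/2)\,S_{aq}/\mu_{adult} = r_m^{T_{gen}}$ for the shared daily
  aquatic survival fixes $\mu_{aq}$ (about 0.153/day at the defaults,
  lifetime reproduction about 9.1). This single quantity controls how much
  density compensation a suppression intervention must overcome, which is
  why we prefer it to three unconstrained stage mortalities (overridable).
* **$\alpha$ in closed form.** Stationarity of the all-wild-type population
  at $N_{eq}$ fixes the required egg-to-adult survival, hence the
  equilibrium larval daily survival, hence $\alpha$ algebraically — no
  numerical solve, and the returned equilibrium state is an exact fixed
  point of the deterministic update (verified to $10^{-9}$ in the tests).

Fitness costs are dominant and additive across cost-bearing allele classes:
a genotype's multiplier is $w = 1 - \sum_i s_i$, floored at 0.05. The
fecundity channel multiplies $\beta$ by $w$; the longevity channel
multiplies the daily adult *mortality* by $1/w$, so the expected lifespan —
and hence lifetime matings or egg batches — scales by $w$. Costs are
therefore per-generation selection coefficients in both channels; applying
$w$ to daily survival instead would compound an intended 5% cost into a
~25% per-generation deficit at an 8-day lifespan.

## Design choices

Several points were genuinely open; the package settles them as follows.

**X-shredder fertility coupling.** `shredder_params(fertility_cost = NULL)`
destroys gametes without renormalization: the cross's realized fecundity is
the surviving-gamete mass (0.5 for a perfect Y-linked shredder), and the
fertility reduction emerges mechanically. Under this coupling a Y-linked
shredder is exactly frequency-neutral — a carrier male sires $\beta/2$ sons
per mating regardless of efficiency — so it suppresses only while release
males dominate matings. Real mosquito matings are not sperm-limited, and
X-shredder males show at most modest fertility loss, so the bundled
scenarios use the sperm-excess mode instead: the sex-ratio bias of the
surviving gametes stands, and shredder-sired crosses lose only an explicit
`fertility_cost` (stand-in 0.05). This restores the classic driving-Y
advantage (carrier males sire nearly twice as many sons) on which fast
suppression depends.

**Leaky somatic expression in the homing suppression drive.** Fertile
females carrying the homing construct suffer a somatic fecundity reduction
(`somatic_cost`, default 0.5): leaky nuclease expression mosaically disrupts
the fertility target in the carrier herself. This is the characteristic drag
reported for fertility-gene homing drives and is what makes the homing
system reach elimination more slowly than the Y-linked shredder in the
bundled comparison.

**Maternal deposition.** The split-drive scenarios set $d = 0.5$ for all
three Cas9 linkages. The Y-linked system is unaffected *by construction* —
Cas9 never occurs in a mother — so the premise that Y-linkage avoids
maternal-carryover resistance emerges structurally rather than through
per-architecture switches. The architecture-builder default remains $d = 0$.

**Resistance partition.** A single resistance rate $\rho$ splits 1/3
in-frame (R) : 2/3 out-of-frame (B), the usual reading-frame convention;
both fractions are configurable.

**Mean-trajectory metrics.** The window of protection and carrier-frequency
summaries are computed on the across-repetition mean trajectory (per-rep
values retained); both the total days above threshold and the longest
contiguous run are reported, with the total as the headline number.

**Migration conversion.** The per-generation rate $m$ becomes a daily
probability $m/T_{gen}$; only adults move, mated females carrying their
mate's genotype with them. This is the simplest unbiased conversion and is
isolated in `migration_matrix()` so it can be swapped.

**Random numbers.** Each repetition runs on a seed drawn deterministically
from the master seed, so results are independent of repetition order and
reproducible bit-for-bit from the run manifest (config hash + seed).

## The bundled scenarios and their stand-in parameters

The scenario generator (`make_sim_fixture()`, `default_configs()`)
reproduces the standard study conditions: two patches of 10,000 adults
exchanging 1% of adults per generation, with 12 weekly releases of 10,000
drive males into patch 1. The `scale` argument shrinks population and
release sizes jointly (a scale-0.05 fixture releases 500 males weekly into a
500-adult patch), preserving the release ratio so that test runs finish in
seconds.

The published source for this scenario family prints only two drive
parameters — cleavage 0.99 and resistance $10^{-6}$ per heterozygote for the
suppression systems; the remaining drive efficiencies and fitness costs live
in supplementary material that is not reproduced here. Those values are
therefore **documented stand-ins**, chosen once so that the deterministic
scenario lies in the published qualitative regime (all split drives peak
above 95% female carrier frequency with a finite window of protection; both
non-localized suppression systems reach elimination; the autosomal shredder
is transient), and expected to be replaced by the supplementary values where
exact numeric agreement is wanted:

* split drives — cleavage 0.99, HDR fraction 0.95, resistance $10^{-3}$,
  deposition 0.5; costs: Cas9 0.15, effector 0.05, B 0.10 (fecundity +
  longevity);
* X-shredders — efficiency 1.0 (a multi-target shredder), X-resistance
  $10^{-6}$, fertility cost 0.05, construct cost 0.025 (longevity only);
* homing suppression — cleavage 0.99, HDR 1, resistance $10^{-6}$, construct
  cost 0.025 (longevity only), somatic cost 0.5.

With these stand-ins the desk-scale comparisons (scale 0.05, 20
repetitions, seeds as in `tests/testthat/test-acceptance.R`) reproduce the
published orderings: the window of protection and the neighboring-patch
carrier frequency both rank Y-linked > autosomal > X-linked Cas9; the
Y-linked shredder eliminates faster than the homing drive and both do so in
most repetitions; the autosomal shredder only suppresses transiently and
rebounds. Absolute durations differ from the published full-parameter runs
(as expected with stand-in costs) and are reported by
`scripts/acceptance.R` rather than asserted.

## What the synthetic data do and do not emulate

`simulate_cross_counts()` draws F1 counts exactly as the cross tables were
generated: a multinomial over the Mendelian class distribution followed by
binomial survival of lethal classes at $1-$penetrance. It emulates sampling
noise and partial penetrance; it does not emulate between-vial
overdispersion, so a real replicate series may be noisier than the
generator.

The simulation fixtures emulate demographic stochasticity, drive genetics,
releases and migration at reduced scale. Scaling down populations makes
stochastic extinction *relatively* easier (absolute thresholds shrink), so
desk-scale elimination probabilities and times are not the full-scale
numbers; orderings between architectures are the robust, scale-stable
comparison, which is why the tests assert orderings and not magnitudes.
They do not model seasonality, spatial structure beyond discrete patches,
genotype-specific larval competition, or an epidemiological layer.

## Numerical and degenerate-input behavior

* Tensor rows are renormalized only over positive mass; an all-destroyed
  gamete set yields a zero row and zero fecundity rather than NaN.
* Carrier frequencies on days with no females alive are `NA` (flagged
  missing), never 0/0.
* Elimination requires *every* life stage in the patch to be zero; the
  state is absorbing and tested as such.
* An infeasible life history (required juvenile survival above the
  density-independent maximum, i.e. $r_m^{T_{gen}} < 1$ equivalent) is
  rejected at construction with a diagnostic message.
* Fitness multipliers are floored (default 0.05) so stacked costs cannot
  produce negative rates; penetrance estimation refuses unidentifiable
  inputs (no lethal class, or survivors only in lethal classes).

## Known limitations

The mating system is single-mating at eclosion with a well-mixed male pool;
no re-mating, sperm competition or mating delay. Resistance is a single
aggregate rate per locus — multiplexed gRNAs with partial resistance are out
of scope. The X chromosome carries a single shred-susceptibility state, not
per-target-site genetics. Fitness costs are dominant and additive; epistasis
and recessive costs are not modeled. Finally, all full-scale quantitative
targets that depend on unpublished supplementary parameter values are
conditional on those values; the package ships stand-ins and the
configuration surface to replace them.
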