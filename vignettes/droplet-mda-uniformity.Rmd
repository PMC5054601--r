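---
title: "Simulating and scoring droplet-partitioned MDA of mock metagenomes"
author: "dropmda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring droplet-partitioned MDA of mock metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropmda)
```

## The problem

Metagenomic sequencing of low-biomass samples — environments that yield
picograms rather than nanograms of DNA — requires whole-genome amplification
before library preparation. Multiple displacement amplification (MDA), the
workhorse method, is notoriously uneven: some template molecules amplify
thousands-fold faster than others, so after sequencing a mixed-species
sample, rare community members are under-represented and coverage depth
along each genome is highly skewed. Partitioning the MDA reaction into
millions of picoliter emulsion droplets changes the dynamics: with a mean
occupancy of one template molecule or fewer per droplet, most templates
amplify alone, saturate their droplet's reagent budget, and end up at
nearly the same copy number regardless of how fast they amplify. The
species distribution and the per-genome coverage depth are both evened out.

`dropmda` provides (i) a stochastic simulator of this mechanism — bulk
versus droplet-partitioned MDA of a defined mock community, through to
paired-end reads with chimeras, contamination and multi-mappers — and
(ii) the analysis pipeline used to compare amplification strategies:
read filtering, subsampling to equal data and to a fixed mean coverage,
coverage breadth, coefficient of variation (CV), Lorenz curves and Gini
coefficients, and species-abundance recovery. The simulator generates
every input the pipeline consumes, so the whole comparison runs on a desk
in seconds; the pipeline equally accepts real per-base depth tables
(`samtools depth` dialect) or minimal SAM-subset alignments.

## The simulation model

**Template pool.** A mock community is a set of reference genomes with
relative input-DNA mass fractions. Genomic DNA enters the reaction as
fragments: each of `n` template molecules picks its genome with probability
equal to the mass fraction (fragment counts track mass when all members
share one fragment-length distribution), a length from a truncated normal,
and a uniform start position.

**Droplet loading.** Each template lands in a uniformly random droplet out
of `droplet_count = reaction_volume / droplet_volume`, so occupancy counts
are Poisson with mean `lambda = n / droplet_count`, and the fraction of
occupied droplets is `1 - exp(-lambda)`. These closed forms are asserted in
the test suite by chi-square goodness of fit and binomial bands.

**Amplification gains.** Template `i` draws a raw gain
`g_i = gain_scale * Lognormal(0, gain_sigma)`. The lognormal has unit
median, so `gain_scale` is the median fold-amplification of an uninhibited
template (MDA routinely delivers thousands-fold; the default is 2000), and
`gain_sigma` sets tail heaviness — the single knob behind winner-take-most
amplification bias. The lognormal is the minimal heavy-tailed choice; only
the tail heaviness, not the exact shape, matters for the qualitative
behavior.

**Competition.** Reagents are finite. In **bulk**, one global copy budget
(`reaction_capacity`) is allocated across all templates by a multinomial
draw with probabilities proportional to the raw gains — fast templates
inhibit everything else. In **emulsion**, the same rule applies per droplet
with budget `droplet_capacity`: a template alone in its droplet saturates at
the budget whenever its gain exceeds it, so at low occupancy most templates
reach the same copy number. The **unamplified** control keeps one copy per
template. When a budget does not bind, copies are the rounded raw gains.
This reproduces the characteristic yield signature: bulk yield is
capacity-limited and flat in input concentration (even a no-template
control amplifies contamination and primer artifacts to full yield), while
emulsion yield tracks the occupied-droplet fraction and falls once
`lambda < 1`.

**Sequencing.** Read pairs sample templates proportionally to
`copies x length`, then place both mates inside the source fragment at the
drawn insert size. Artifacts are injected per pair: *chimeras* (the second
mate comes from an independent template; never properly paired),
*contamination / primer-dimer artifacts* (unmapped, `genome_id =
"artifact"`), and *multi-mappers* (`mapq = 0`, the aligner convention).
Default rates (chimera 0.7% unamplified / 5% amplified arms, contamination
0.4% / 2%, multi-mapping 2%) were chosen so the simulated mapping table
looks like a real mock-community run: >99% of unamplified pairs properly
paired, ~95% in the amplified arms, >98% mapped.

## The analysis pipeline

`run_experiment()` mirrors how mixed-species amplification benchmarks are
analyzed:

1. **Mapping statistics** on the raw libraries (percent mapped, percent of
   mapped pairs properly paired) — chimera formation shows up as the
   properly-paired deficit.
2. **Filtering**: reads not paired in sequencing are removed, then reads
   with mapping quality 0 (multi-mappers). The MAPQ threshold is exactly
   zero; `mapq = 1` survives. Both filters are idempotent and commute.
3. **Equal-data subsampling**: every library is downsampled, at whole-pair
   granularity and without replacement, to the total base count of the
   smallest library ("amount of data" is bases, not pairs, so the rule is
   robust to unequal read lengths). Species proportions (proper pairs per
   genome) and per-genome coverage breadth are computed on this subsample.
4. **Coverage-target subsampling**: per genome, properly paired,
   MAPQ-filtered pairs are subsampled to `floor(target_depth * L / (2 *
   read_length))` pairs — an average 5x coverage by default. Genomes with
   too few pairs are reported as unavailable rather than failing the run;
   with realistic abundance staircases this regularly happens for the
   rarest members, especially in the bulk arm.
5. **Uniformity statistics** on the 5x depth vector: breadth at 1x, CV,
   and the Gini coefficient of the Lorenz curve.

### Lorenz curve and Gini: conventions

Positions are sorted by ascending depth; the curve plots cumulative mapped
bases against cumulative positions, from (0,0) to (1,1). The default basis
restricts the x-axis to positions covered at least once (`covered_only`),
matching how coverage Lorenz plots are usually drawn when breadth is
reported separately; `whole_genome` is available. The area under the
piecewise-linear curve is computed with the Riemann middle sum, which is
exact for linear segments — the test suite asserts equality with a
shoelace polygon-area oracle to 1e-12.

Two Gini scales exist in the wild: the raw area between the diagonal and
the curve (maximum 0.5) and the conventional `2 x area` (maximum 1).
Reported coverage Gini values around 0.5 for visibly skewed bulk-MDA
samples are only consistent with the `2 x` convention, so `standard` is the
default and `area` an explicit option; the package does not silently
resolve the ambiguity.

The CV is the population standard deviation of per-position depth divided
by the mean, across the entire genome including zero-depth positions.
Population (divide by `N`) rather than sample standard deviation is pinned
for exact reproducibility; at genome scale the difference is negligible.

## Desk scaling: why the defaults are what they are

The defaults shrink a physical experiment (~5-Mb genomes, microliters of
emulsion, ~10^7 droplets) by roughly two orders of magnitude so a full
three-arm replicate runs in under a second:

| parameter | default | rationale |
|---|---|---|
| genomes | 5 x 50 kb, GC 0.54-0.66 | five-member community, 100x scaled-down genomes |
| mass fractions | 0.45/0.30/0.15/0.07/0.03 | a staircase spanning 15x, with a genuinely rare member |
| droplet volume | 10 pl | typical flow-focusing droplet (26 um diameter) |
| reaction volume | 0.2 ul → 2e4 droplets | scaled with the genomes, see below |
| lambda | 0.2 | "one molecule or fewer per droplet" regime |
| fragment length | 500 +/- 50 bp | 1% of genome length, the fragment:genome ratio of tens-of-kb templates on Mb genomes |
| gain_sigma | 2 | heavy-tailed enough for winner-take-most bulk behavior |
| gain_scale | 2000 | median fold-gain of uninhibited MDA |
| droplet_capacity | 400 copies | see calibration note below |
| reads | 150 bp paired, 300 +/- 20 bp insert | desk-scale stand-in for 2 x 300 bp libraries |
| libraries | 24k/22k/20k pairs | unequal on purpose, so equal-data subsampling does real work |
| target depth | 5x | the comparison depth for CV/Gini |

The one quantity that must be scaled *jointly* is template redundancy: the
number of template molecules overlapping a genome position,
`m_g = n_g * fragment_length / genome_length`. Per-template gain dispersion
shows up in coverage depth attenuated by `1/sqrt(m_g)`; with tens of
thousands of droplets at `lambda = 0.2` over 50-kb genomes, `m` ranges from
~18 (dominant member) down to ~1 (rarest member, i.e. barely one genome
equivalent in the pool — exactly the "minute amounts of DNA" regime the
method targets). Keeping the droplet count at its physical order while
shrinking the genomes 100x would push `m` into the thousands, where any
per-template bias averages out and all three arms look identical — the
simulation would be scaled inconsistently.

`droplet_capacity` relative to `gain_scale` balances two regimes: if the
budget is far below the median gain, virtually every occupied droplet
saturates and the emulsion arm becomes indistinguishable from the
unamplified control; if it is close, the bulk reaction's capacity stops
binding at the lowest input concentrations and the bulk yield plateau — a
signature behavior — disappears. The default ratio (400 vs 2000) keeps the
bulk plateau capacity-limited down to `lambda = 0.04` while leaving the
emulsion arm ~25% of droplets short of saturation, a realistic,
detectable residue of amplification bias.

These are the study conditions; they are set once here, not tuned per
analysis.

## What a passing test run does and does not show

The simulator reproduces the *mechanisms* the droplet-partitioning argument
rests on — Poisson occupancy, per-droplet saturation, global versus local
competition, chimera/contamination bookkeeping — and the pipeline's
statistics are exact by construction. Passing tests therefore show that
under these mechanisms, partitioning preserves the species distribution
(smaller L1 distance to truth, higher rare-member breadth) and evens
coverage (per-genome Gini and CV medians order unamplified < emulsion <
bulk), and that the analysis code computes what it claims.

They do not show anything about features of real data the generator leaves
out: locus-correlated amplification bias (primer landing and GC effects
that make neighboring positions amplify together — in real data this, not
per-template dispersion alone, carries much of the unevenness),
polymerase base errors, library-preparation GC bias, alignment ambiguity
beyond a constant multi-mapping rate, or reference errors such as
duplicated regions. Real-data conclusions still require the real-data
entry points (`read_depth_tsv()`, `read_alignments()`).

One quantitative caveat is worth stating plainly. In this model the bulk
arm's copy budget is allocated proportionally to i.i.d. heavy-tailed
gains, which preserves each species' *expected* share exactly; rare-member
suppression appears only through the skew of the share distribution (the
median falls below the truth, but occasional replicates overshoot when a
rare template draws a huge gain). The *direction* "rare member's recovered
proportion is higher in emulsion than in bulk" therefore holds in roughly
three quarters to four fifths of replicates — not near-always, the way the
breadth and L1 comparisons do. Reproducing near-deterministic proportion
suppression would require a mechanism that couples gain to abundance or
compounds competition over time, which the present model deliberately does
not include.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based, half-open everywhere internally; conversion to
  1-based happens only at SAM and depth-TSV boundaries.
* All randomness flows through R's generator; every public operation takes
  a `seed`, restores the caller's RNG state, and `run_experiment()` derives
  everything from one master seed recorded in the report manifest, so
  reports regenerate bit-for-bit.
* Ties in depth sorting are broken by position index (irrelevant to every
  statistic, which are position-exchangeable, but it pins determinism).
* Pair counts are floored, never rounded, in both subsampling rules; the
  equal-data rule leaves libraries within one pair's bases of each other.
* Degenerate inputs raise typed conditions rather than returning
  conventional values: an all-zero depth vector has no Lorenz curve and no
  CV (`dropmda_undefined_statistic`); a library too small for the coverage
  target raises `dropmda_insufficient_pairs` carrying the required and
  available counts; empty record sets give `NA` mapping fractions, not 0.
* `amplify_bulk` requires `reaction_capacity >= n` templates; zero-template
  pools short-circuit to zero yield.

## Problem sizes

The bundled tests and the acceptance script run the default configuration
at 20 replicates (three arms each; about half a minute), statistic oracles
on 1000 random small vectors, occupancy goodness of fit on 1e5 droplets,
and yield curves on 1e5 droplets — sizes chosen so the full suite completes
in a few minutes while every stochastic assertion retains 3-sigma-style
power.

## A worked example

```{r example}
report <- run_experiment(default_config(), seed = 42)
report$mapping
subset(report$uniformity, available)
```

The per-genome rows mirror a coverage-characteristics table: breadth at
1x after 5x subsampling, CV percent, and Gini. The bulk arm's Gini roughly
doubles the unamplified control's, with the emulsion arm close to the
control — the quantitative core of the case for partitioned amplification.
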