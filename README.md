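# dropmda

Simulation and coverage-uniformity analysis of droplet-partitioned versus
bulk multiple displacement amplification (MDA) of mock metagenomic
communities.

## The problem

MDA is the standard whole-genome amplification method when a metagenomic
sample contains only picograms of DNA, but it amplifies unevenly: a few
template molecules win the reaction, rare species shrink or vanish, and
coverage depth along each genome becomes highly skewed. Partitioning the
reaction into millions of picoliter emulsion droplets — with on average one
template molecule or fewer per droplet — lets most templates amplify in
isolation and saturate a fixed per-droplet budget, which preserves the
species distribution and evens out coverage.

`dropmda` is for people who want to study or teach that mechanism, or to
score amplification uniformity in their own data. It provides:

* a **stochastic simulator** of bulk vs emulsion MDA of a defined mock
  community: Poisson loading of templates into droplets, heavy-tailed
  per-template gains `g_i = gain_scale · Lognormal(0, σ)`, a multinomial
  copy-budget competition (global in bulk, per droplet in emulsion), and
  paired-end read generation with chimeras, contamination artifacts and
  multi-mappers, written out as FASTA/FASTQ/SAM/TSV if desired;
* the **analysis pipeline** such comparisons use: unpaired-read and MAPQ-0
  filters, subsampling to equal data and to a 5× mean coverage target,
  mapping statistics, species-abundance tables, coverage breadth, and
  per-genome uniformity statistics — coefficient of variation
  `CV = 100 · sd(depth)/mean(depth)` over all positions, and the Gini
  coefficient `G = 2 · area between the Lorenz curve and the diagonal`,
  with the Lorenz curve built from positions sorted by ascending depth
  and the area taken by the Riemann middle sum (exact for the piecewise
  linear curve).

Real data enter through `read_depth_tsv()` (samtools-depth dialect) or
`read_alignments()` (minimal SAM subset or the package's truth TSV).

## A worked example

One seeded replicate of the three-arm experiment — unamplified control,
MDA in emulsion, MDA in bulk — on the default five-member community
(50-kb genomes, mass fractions 0.45/0.30/0.15/0.07/0.03, λ = 0.2):

```r
library(dropmda)
report <- run_experiment(default_config(), seed = 42)

report$mapping
#    sample_id total_pairs mapped_fraction properly_paired_fraction
#  unamplified       24000        99.66250                 99.34780
#     emulsion       22000        97.95909                 94.90511
#         bulk       20000        98.13000                 95.07796
```

The properly-paired deficit in the amplified arms is the chimera rate the
simulator injected. Per-genome uniformity after subsampling each genome to
5× mean coverage (genomes with too few proper pairs are reported as
unavailable, which regularly befalls the rarest member):

```r
subset(report$uniformity, available)
#    sample_id genome_id available breadth_percent cv_percent      gini
#  unamplified  genome_1      TRUE          97.308   57.33288 0.2949637
#  unamplified  genome_2      TRUE          96.934   56.11050 0.2928679
#  unamplified  genome_3      TRUE          95.856   65.72852 0.3320411
#  unamplified  genome_4      TRUE          81.124   92.01384 0.3784386
#     emulsion  genome_1      TRUE          97.984   51.28452 0.2714460
#     emulsion  genome_2      TRUE          98.628   55.67489 0.2977938
#     emulsion  genome_3      TRUE          96.024   66.38822 0.3366451
#     emulsion  genome_4      TRUE          80.130   92.57302 0.3783122
#         bulk  genome_1      TRUE          90.530  125.88459 0.4916221
#         bulk  genome_2      TRUE          86.528  130.36874 0.4783806
#         bulk  genome_3      TRUE          78.942  143.79277 0.5349501
#         bulk  genome_4      TRUE          54.610  327.69051 0.6860169
```

Bulk amplification roughly doubles the Gini coefficient and the CV of
every genome relative to the unamplified control, while the emulsion arm
stays close to the control; the bulk arm also loses coverage breadth. The
recovered species proportions at equal data tell the same story — here the
rarest member keeps its ~3% share through emulsion amplification
(0.0242 vs truth 0.03) but drops to 0.0154 in bulk.

Individual pieces are exported on their own, e.g.

```r
d <- depth_vector("chr", c(1, 1, 2, 4))
gini(d)                       # 0.3125
coefficient_of_variation(d)   # 61.237
lorenz_curve(d)               # polyline from (0,0) to (1,1)
```

A thin command-line wrapper with `run`, `simulate` and `uniformity`
subcommands is installed at `inst/scripts/emda.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/emda.R", package="dropmda"))')" \
    simulate --mode emulsion --seed 1 --out-dir sim/
```

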