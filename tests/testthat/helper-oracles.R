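# Independent oracles and small fixture builders shared across test files.

# Gini via the shoelace (polygon) area of the region enclosed by the Lorenz
# polyline and the diagonal — an independent route to the same area the
# midpoint rule computes.
gini_shoelace <- function(depth, basis = "covered_only", scale = "standard") {
  d <- depth
  if (basis == "covered_only") d <- d[d > 0]
  d <- sort(d)
  x <- c(0, seq_along(d) / length(d))
  y <- c(0, cumsum(d) / sum(d))
  # close the polygon along the diagonal from (1,1) back to (0,0)
  px <- c(x, 0)
  py <- c(y, 0)
  area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  if (scale == "standard") 2 * area else area
}

# Direct two-pass population CV, in percent.
cv_twopass <- function(d) {
  m <- sum(d) / length(d)
  100 * sqrt(sum((d - m)^2) / length(d)) / m
}

# Minimal pair-level alignment records with sensible defaults.
make_pairs <- function(n, genome_id = "g", mate1_start = 0L,
                       mate2_start = 10L, read_length = 5L,
                       is_proper = TRUE, is_chimera = FALSE,
                       is_mapped = TRUE, mapq = 60L, paired = TRUE,
                       mate2_genome_id = genome_id) {
  data.frame(pair_id = seq_len(n),
             genome_id = rep_len(genome_id, n),
             mate2_genome_id = rep_len(mate2_genome_id, n),
             mate1_start = as.integer(rep_len(mate1_start, n)),
             mate2_start = as.integer(rep_len(mate2_start, n)),
             read_length = as.integer(rep_len(read_length, n)),
             insert_size = as.integer(rep_len(mate2_start + read_length -
                                                mate1_start, n)),
             paired = rep_len(paired, n),
             is_mapped = rep_len(is_mapped, n),
             is_proper = rep_len(is_proper, n),
             is_chimera = rep_len(is_chimera, n),
             mapq = as.integer(rep_len(mapq, n)),
             stringsAsFactors = FALSE)
}

# One-genome community with an unamplified template pool, for read-level
# conservation checks.
simulate_single_genome_reads <- function(n_pairs, genome_length = 20000L,
                                         n_templates = 400L,
                                         read_length = 100L,
                                         insert_mean = 300L, seed = 1,
                                         chimera_rate = 0,
                                         contamination_rate = 0,
                                         multimap_rate = 0) {
  genomes <- generate_mock_genomes(1, genome_length, 0.5, seed = seed,
                                   ids = "g")
  comm <- mock_community("g", 1)
  tpl <- fragment_templates(comm, genomes, n_templates, 2000, seed = seed)
  amp <- amplify_none(tpl)
  list(genomes = genomes, templates = tpl,
       records = generate_reads(amp, tpl, genomes, n_pairs, read_length,
                                insert_mean, chimera_rate = chimera_rate,
                                contamination_rate = contamination_rate,
                                multimap_rate = multimap_rate, seed = seed + 1))
}

# Small three-arm configuration for fast pipeline tests.
small_config <- function() {
  cfg <- default_config()
  cfg$genome_length <- 20000L
  cfg$reaction_volume_ul <- 0.05       # 5000 droplets, 1000 templates
  cfg$n_pairs <- c(unamplified = 5000L, emulsion = 4500L, bulk = 4000L)
  cfg
}
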