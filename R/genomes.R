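#' Generate random mock-community reference genomes
#'
#' Draws `n` genome sequences with i.i.d. bases at the requested GC content,
#' as stand-ins for the reference genomes of a defined mock community (a
#' synthetic metagenome mixes purified genomic DNA from a handful of known
#' species). Sequences are returned as a named [Biostrings::DNAStringSet].
#'
#' @param n Number of genomes.
#' @param lengths Integer vector of genome lengths in bp, one per genome
#'   (each at least 1000).
#' @param gc Numeric vector of target GC fractions in `[0, 1]`, one per genome.
#' @param seed Optional integer seed; a fixed seed gives byte-identical output.
#' @param ids Genome identifiers; defaults to `"genome_1"`, `"genome_2"`, ...
#' @return A `DNAStringSet` of length `n`, named by `ids`.
#' @examples
#' g <- generate_mock_genomes(2, lengths = c(2000, 3000), gc = c(0.4, 0.6), seed = 1)
#' Biostrings::width(g)
#' @export
generate_mock_genomes <- function(n, lengths, gc, seed = NULL,
                                  ids = sprintf("genome_%d", seq_len(n))) {
  if (length(lengths) != n || length(gc) != n || length(ids) != n)
    stop_argument("`lengths`, `gc` and `ids` must each have length `n`")
  if (any(lengths < 1000))
    stop_argument("genome lengths must be at least 1000 bp")
  check_fraction(gc, "gc")
  if (anyDuplicated(ids)) stop_argument("genome ids must be unique")
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2, T = (1 - gc[i]) / 2)
      paste(sample(names(p), lengths[i], replace = TRUE, prob = p), collapse = "")
    }, character(1))
    setNames(Biostrings::DNAStringSet(seqs), ids)
  })
}

#' Genome lengths of a reference set
#'
#' @param genomes A named `DNAStringSet` (as from [generate_mock_genomes()])
#'   or an already-named integer vector of lengths.
#' @return Named integer vector of genome lengths in bp.
#' @export
genome_lengths <- function(genomes) {
  if (methods::is(genomes, "DNAStringSet"))
    return(setNames(Biostrings::width(genomes), names(genomes)))
  if (is.numeric(genomes) && !is.null(names(genomes)))
    return(setNames(as.integer(genomes), names(genomes)))
  stop_argument("`genomes` must be a named DNAStringSet or a named length vector")
}

#' Define a mock community by relative input DNA mass
#'
#' A mock community is a defined mixture of genomic DNA from known species at
#' known relative mass fractions; it provides the ground truth against which
#' amplified samples are compared.
#'
#' @param genome_ids Character vector of member genome identifiers.
#' @param mass_fractions Positive fractions of input DNA mass, summing to 1
#'   (within 1e-9).
#' @return A `data.frame` with columns `genome_id`, `mass_fraction`, of class
#'   `mock_community`.
#' @examples
#' mock_community(c("a", "b"), c(0.9, 0.1))
#' @export
mock_community <- function(genome_ids, mass_fractions) {
  if (length(genome_ids) != length(mass_fractions) || length(genome_ids) < 1)
    stop_argument("`genome_ids` and `mass_fractions` must be non-empty and equal length")
  if (any(mass_fractions <= 0))
    stop_argument("all mass fractions must be > 0")
  if (abs(sum(mass_fractions) - 1) > 1e-9)
    stop_argument("mass fractions must sum to 1 (within 1e-9)")
  if (anyDuplicated(genome_ids)) stop_argument("community genome ids must be unique")
  structure(
    data.frame(genome_id = as.character(genome_ids),
               mass_fraction = as.numeric(mass_fractions),
               stringsAsFactors = FALSE),
    class = c("mock_community", "data.frame"))
}

#' Fragment community DNA into template molecules
#'
#' Genomic DNA enters an amplification reaction as fragments; this draws
#' `total_templates` template molecules whose genome of origin follows the
#' community mass fractions (fragment counts track mass fractions because all
#' members share one fragment-length distribution) and whose start positions
#' are uniform over valid positions.
#'
#' Fragment lengths are drawn from a normal distribution with mean
#' `fragment_length_mean` and standard deviation `fragment_length_sd`,
#' truncated to `[fragment_length_mean / 2, fragment_length_mean * 2]` and to
#' the genome length, so every template can host a full sequencing insert.
#'
#' @param community A [mock_community()].
#' @param genomes Reference genomes (`DNAStringSet` or named length vector).
#' @param total_templates Number of template molecules to draw (>= 1).
#' @param fragment_length_mean Mean fragment length in bp; must not exceed the
#'   shortest member genome.
#' @param fragment_length_sd Standard deviation of fragment length in bp
#'   (default one tenth of the mean; 0 gives fixed-length fragments).
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `template_id`, `genome_id`, `start`
#'   (0-based), `length`, `is_contaminant`.
#' @export
fragment_templates <- function(community, genomes, total_templates,
                               fragment_length_mean,
                               fragment_length_sd = fragment_length_mean / 10,
                               seed = NULL) {
  if (!inherits(community, "mock_community"))
    stop_argument("`community` must be a mock_community")
  lens <- genome_lengths(genomes)
  missing <- setdiff(community$genome_id, names(lens))
  if (length(missing))
    stop_argument(paste("community members missing from genomes:",
                        paste(missing, collapse = ", ")))
  if (total_templates < 1) stop_argument("`total_templates` must be >= 1")
  if (fragment_length_mean > min(lens[community$genome_id]))
    stop_argument("`fragment_length_mean` exceeds the shortest member genome")
  with_seed(seed, {
    idx <- sample.int(nrow(community), total_templates, replace = TRUE,
                      prob = community$mass_fraction)
    gid <- community$genome_id[idx]
    glen <- unname(lens[gid])
    flen <- if (fragment_length_sd > 0) {
      round(rnorm(total_templates, fragment_length_mean, fragment_length_sd))
    } else rep(fragment_length_mean, total_templates)
    flen <- pmax(pmin(flen, round(2 * fragment_length_mean), glen),
                 round(fragment_length_mean / 2))
    start <- floor(runif(total_templates) * (glen - flen + 1))
    data.frame(template_id = seq_len(total_templates),
               genome_id = gid,
               start = as.integer(start),
               length = as.integer(flen),
               is_contaminant = FALSE,
               stringsAsFactors = FALSE)
  })
}
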