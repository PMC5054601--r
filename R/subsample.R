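#' Bundle alignment records of one sequencing library
#'
#' @param sample_id Sample label.
#' @param records Pair-level alignment `data.frame`.
#' @param read_length Read length in bp.
#' @return A list of class `sample_read_set` with `sample_id`, `records`,
#'   `read_length` and `total_bases` (`2 * read_length * n_pairs`).
#' @export
sample_read_set <- function(sample_id, records, read_length) {
  structure(list(sample_id = as.character(sample_id),
                 records = records,
                 read_length = as.integer(read_length),
                 total_bases = 2 * as.numeric(read_length) * nrow(records)),
            class = "sample_read_set")
}

#' @export
print.sample_read_set <- function(x, ...) {
  cat(sprintf("<sample_read_set> %s: %d pairs, %d bp reads, %.3g bases\n",
              x$sample_id, nrow(x$records), x$read_length, x$total_bases))
  invisible(x)
}

#' Remove reads that were not paired in sequencing
#'
#' Keeps only records for which both mates exist. Idempotent, and commutes
#' with [filter_multimapped()].
#'
#' @param records Pair-level alignment `data.frame`.
#' @return The paired subset, row order preserved.
#' @export
filter_unpaired <- function(records) {
  records[records$paired, , drop = FALSE]
}

#' Remove multi-mapping reads
#'
#' Drops records with mapping quality 0 — the aligner convention for reads
#' mapping equally well to more than one location. The threshold is exactly
#' 0: `mapq = 1` survives. Idempotent, and commutes with
#' [filter_unpaired()].
#'
#' @param records Pair-level alignment `data.frame`.
#' @return The subset with `mapq > 0`, row order preserved.
#' @export
filter_multimapped <- function(records) {
  records[records$mapq > 0, , drop = FALSE]
}

#' Subsample libraries to the same amount of data
#'
#' Sequencing libraries differ in size; to compare coverage between samples
#' fairly, each library is downsampled — uniformly at random, without
#' replacement, at whole-pair granularity — to the total base count of the
#' smallest library ("amount of data" is bases, `pairs * 2 * read_length`,
#' so the rule stays correct if read lengths ever differ between libraries).
#'
#' @param samples List of [sample_read_set()] objects (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   selection.
#' @return List of `sample_read_set` objects in the input order, each holding
#'   `floor(target_bases / (2 * read_length))` pairs.
#' @export
equal_data_subsample <- function(samples, seed = NULL) {
  if (!length(samples)) stop_argument("need at least one sample")
  stopifnot(all(vapply(samples, inherits, TRUE, "sample_read_set")))
  target <- min(vapply(samples, `[[`, numeric(1), "total_bases"))
  with_seed(seed, {
    lapply(samples, function(s) {
      keep_n <- floor(target / (2 * s$read_length))
      if (keep_n < nrow(s$records)) {
        keep <- sort(sample.int(nrow(s$records), keep_n))
        s <- sample_read_set(s$sample_id, s$records[keep, , drop = FALSE],
                             s$read_length)
      }
      s
    })
  })
}

#' Subsample one genome's proper pairs to a target mean coverage
#'
#' Selects `floor(target_depth * genome_length / (2 * read_length))` pairs
#' uniformly at random without replacement, so the retained data correspond
#' to an average `target_depth`x coverage of that genome. Callers supply
#' records already restricted to properly paired reads on the one genome and
#' filtered of multi-mappers ([filter_multimapped()]).
#'
#' When the library holds fewer pairs than required, a typed condition of
#' class `dropmda_insufficient_pairs` is raised naming the required and
#' available counts — for rare community members, deep-coverage comparisons
#' are often only possible for the most abundant species.
#'
#' @param records Proper-pair records on a single genome.
#' @param genome_length Genome length in bp.
#' @param read_length Read length in bp.
#' @param target_depth Target mean coverage (default 5).
#' @param seed Optional integer seed.
#' @return The selected records, in original row order.
#' @export
target_coverage_subsample <- function(records, genome_length, read_length,
                                      target_depth = 5.0, seed = NULL) {
  required <- floor(target_depth * genome_length / (2 * read_length))
  available <- nrow(records)
  if (available < required) {
    stop(errorCondition(
      sprintf("insufficient pairs for %gx coverage: %d required, %d available",
              target_depth, required, available),
      required = required, available = available,
      class = c("dropmda_insufficient_pairs", "error", "condition")))
  }
  with_seed(seed, {
    keep <- sort(sample.int(available, required))
    records[keep, , drop = FALSE]
  })
}
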