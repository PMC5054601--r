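#' Simulate paired-end reads from an amplified template pool
#'
#' Sequencing-ready read pairs are drawn from templates with probability
#' proportional to `copies * length` (a sequencer samples amplified mass).
#' Both mates of a proper pair fall inside one source fragment at the drawn
#' insert size. Amplification artifacts are injected at configurable rates:
#'
#' * **chimeras** — noncontiguous sequences joined during amplification; the
#'   second mate is drawn from an independent template, so the pair is not
#'   properly paired (`is_proper = FALSE`, `is_chimera = TRUE`);
#' * **contamination / primer-dimer artifacts** — the pair maps to no member
#'   genome (`genome_id = "artifact"`, unmapped);
#' * **multi-mappers** — reads mapping equally well to several locations,
#'   flagged with `mapq = 0` (the aligner convention); all other mapped pairs
#'   carry `mapq = 60`.
#'
#' The returned table doubles as the truth alignment record set: it is the
#' input the coverage and subsampling stages consume.
#'
#' @param amplification An `amplification_result`.
#' @param templates The matching template `data.frame`.
#' @param genomes Reference genomes (`DNAStringSet` or named lengths); used
#'   for validation and by [write_reads_fastq()].
#' @param n_pairs Number of read pairs to draw.
#' @param read_length Read length in bp.
#' @param insert_mean Mean insert size in bp (`read_length <= insert_mean`).
#' @param insert_sd Insert-size standard deviation in bp (default 0: fixed).
#' @param chimera_rate,contamination_rate,multimap_rate Per-pair artifact
#'   probabilities in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with one row per pair: `pair_id`, `genome_id`,
#'   `mate2_genome_id`, `mate1_start`, `mate2_start` (0-based), `read_length`,
#'   `insert_size`, `paired`, `is_mapped`, `is_proper`, `is_chimera`, `mapq`.
#' @export
generate_reads <- function(amplification, templates, genomes, n_pairs,
                           read_length, insert_mean, insert_sd = 0,
                           chimera_rate = 0, contamination_rate = 0,
                           multimap_rate = 0, seed = NULL) {
  stopifnot(inherits(amplification, "amplification_result"))
  check_fraction(c(chimera_rate, contamination_rate, multimap_rate), "rates")
  if (read_length < 1 || insert_mean < read_length)
    stop_argument("need 1 <= read_length <= insert_mean")
  if (n_pairs == 0) return(empty_read_pairs())
  copies <- amplification$copies
  if (!identical(as.integer(amplification$template_id),
                 as.integer(templates$template_id)))
    stop_argument("amplification and templates disagree on template ids")
  weights <- copies * templates$length
  if (all(weights == 0))
    stop(errorCondition("no amplified template mass to sequence from",
                        class = c("dropmda_input_error", "error", "condition")))
  with_seed(seed, {
    src <- sample.int(nrow(templates), n_pairs, replace = TRUE, prob = weights)
    tlen <- templates$length[src]
    tstart <- templates$start[src]
    ins <- if (insert_sd > 0) round(rnorm(n_pairs, insert_mean, insert_sd))
           else rep(insert_mean, n_pairs)
    ins <- pmax(pmin(ins, tlen), read_length)
    offset <- floor(runif(n_pairs) * (tlen - ins + 1))
    m1 <- tstart + offset
    m2 <- m1 + ins - read_length

    is_artifact <- runif(n_pairs) < contamination_rate
    is_chimera <- !is_artifact & runif(n_pairs) < chimera_rate
    is_multi <- runif(n_pairs) < multimap_rate

    gid <- templates$genome_id[src]
    gid2 <- gid
    if (any(is_chimera)) {
      src2 <- sample.int(nrow(templates), sum(is_chimera), replace = TRUE,
                         prob = weights)
      t2len <- templates$length[src2]
      m2[is_chimera] <- templates$start[src2] +
        floor(runif(sum(is_chimera)) * (t2len - read_length + 1))
      gid2[is_chimera] <- templates$genome_id[src2]
      ins[is_chimera] <- NA_integer_
    }
    gid[is_artifact] <- "artifact"
    gid2[is_artifact] <- "artifact"
    m1[is_artifact] <- NA_integer_
    m2[is_artifact] <- NA_integer_
    ins[is_artifact] <- NA_integer_

    is_mapped <- !is_artifact
    is_proper <- is_mapped & !is_chimera
    mapq <- ifelse(is_mapped, ifelse(is_multi, 0L, 60L), 0L)

    data.frame(pair_id = seq_len(n_pairs),
               genome_id = gid,
               mate2_genome_id = gid2,
               mate1_start = as.integer(m1),
               mate2_start = as.integer(m2),
               read_length = as.integer(read_length),
               insert_size = as.integer(ins),
               paired = TRUE,
               is_mapped = is_mapped,
               is_proper = is_proper,
               is_chimera = is_chimera,
               mapq = as.integer(mapq),
               stringsAsFactors = FALSE)
  })
}

empty_read_pairs <- function() {
  data.frame(pair_id = integer(0), genome_id = character(0),
             mate2_genome_id = character(0), mate1_start = integer(0),
             mate2_start = integer(0), read_length = integer(0),
             insert_size = integer(0), paired = logical(0),
             is_mapped = logical(0), is_proper = logical(0),
             is_chimera = logical(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

#' Write a truth table of simulated read pairs
#'
#' Tab-separated, one row per pair, 0-based mate starts (the package's
#' internal convention; conversion to 1-based happens only in SAM and depth
#' TSV output). [read_alignments()] with `dialect = "truth_tsv"` reads it
#' back losslessly.
#'
#' @param records Read-pair `data.frame` from [generate_reads()].
#' @param path Output file path.
#' @export
write_truth_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated read pairs as a minimal SAM file
#'
#' Emits a SAM-compatible subset: `@HD`/`@SQ` headers and the first nine
#' mandatory columns per mate, fixed-length `<read_length>M` CIGAR. Properly
#' paired mates carry flags 99/147; mapped improper (chimeric) mates 97/145;
#' unmapped artifact mates 77/141 with `RNAME *`. MAPQ is honored as-is.
#'
#' @param records Read-pair `data.frame`.
#' @param path Output file path.
#' @param genome_lengths Named vector of reference lengths for `@SQ` lines.
#' @export
write_sam <- function(records, path, genome_lengths) {
  lens <- genome_lengths(genome_lengths)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(records) == 0) return(invisible(path))
  qname <- sprintf("pair%d", records$pair_id)
  rl <- records$read_length
  cigar <- ifelse(records$is_mapped, sprintf("%dM", rl), "*")
  flag1 <- ifelse(records$is_mapped, ifelse(records$is_proper, 99L, 97L), 77L)
  flag2 <- ifelse(records$is_mapped, ifelse(records$is_proper, 147L, 145L), 141L)
  rname1 <- ifelse(records$is_mapped, records$genome_id, "*")
  rname2 <- ifelse(records$is_mapped, records$mate2_genome_id, "*")
  pos1 <- ifelse(records$is_mapped, records$mate1_start + 1L, 0L)
  pos2 <- ifelse(records$is_mapped, records$mate2_start + 1L, 0L)
  tlen <- ifelse(records$is_proper, records$insert_size, 0L)
  seqf <- strrep("N", rl)
  line1 <- paste(qname, flag1, rname1, pos1, records$mapq, cigar,
                 ifelse(rname2 == rname1, "=", rname2), pos2, tlen,
                 seqf, "*", sep = "\t")
  line2 <- paste(qname, flag2, rname2, pos2, records$mapq, cigar,
                 ifelse(rname1 == rname2, "=", rname1), pos1, -tlen,
                 seqf, "*", sep = "\t")
  writeLines(c(rbind(line1, line2)), con)
  invisible(path)
}

#' Write simulated read pairs as paired FASTQ
#'
#' Extracts mate sequences from the reference genomes (mate 2 is written
#' reverse-complemented, as on an Illumina run) with a fixed quality string.
#' Artifact pairs, which have no genomic source, are emitted as random
#' sequence so library-size accounting stays intact.
#'
#' @param records Read-pair `data.frame`.
#' @param genomes Named `DNAStringSet` holding the reference sequences.
#' @param path_r1,path_r2 Output FASTQ paths for mates 1 and 2.
#' @param seed Optional seed for artifact-pair filler sequence.
#' @export
write_reads_fastq <- function(records, genomes, path_r1, path_r2, seed = NULL) {
  stopifnot(methods::is(genomes, "DNAStringSet"))
  n <- nrow(records)
  rl <- if (n) records$read_length[1] else 0L
  get_seq <- function(gid, start) {
    out <- character(length(gid))
    ok <- gid != "artifact" & !is.na(start)
    if (any(ok)) {
      v <- Biostrings::DNAStringSet(unlist(lapply(which(ok), function(i)
        subseq(genomes[[gid[i]]], start[i] + 1L, start[i] + rl))))
      out[ok] <- as.character(v)
    }
    out
  }
  with_seed(seed, {
    s1 <- get_seq(records$genome_id, records$mate1_start)
    s2 <- get_seq(records$mate2_genome_id, records$mate2_start)
    filler <- function(k) vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE), collapse = ""),
      character(1))
    s1[s1 == ""] <- filler(sum(s1 == ""))
    s2[s2 == ""] <- filler(sum(s2 == ""))
    s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s2)))
    qual <- strrep("I", rl)
    ids <- sprintf("@pair%d", records$pair_id)
    writeLines(c(rbind(paste0(ids, "/1"), s1, "+", qual)), path_r1)
    writeLines(c(rbind(paste0(ids, "/2"), s2, "+", qual)), path_r2)
  })
  invisible(c(path_r1, path_r2))
}

subseq <- function(x, start, end) Biostrings::subseq(x, start, end)
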