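#' Per-position coverage depth over one genome
#'
#' @param genome_id Genome identifier.
#' @param depth Non-negative integer vector, one element per genome position.
#' @return An object of class `depth_vector`: list with `genome_id`, `depth`.
#' @export
depth_vector <- function(genome_id, depth) {
  depth <- as.numeric(depth)
  if (any(!is.finite(depth)) || any(depth < 0))
    stop_argument("depth values must be finite and non-negative")
  structure(list(genome_id = as.character(genome_id), depth = depth),
            class = "depth_vector")
}

#' @export
print.depth_vector <- function(x, ...) {
  cat(sprintf("<depth_vector> %s: %d positions, mean depth %.3f, breadth %.2f%%\n",
              x$genome_id, length(x$depth), mean(x$depth), breadth(x)))
  invisible(x)
}

#' Read alignment records
#'
#' Ingests pair-level alignment facts from either of two text dialects:
#'
#' * `"truth_tsv"` — the package's own truth table ([write_truth_tsv()]),
#'   0-based starts, read back losslessly;
#' * `"sam_subset"` — a minimal SAM file (the first nine mandatory columns;
#'   flag bits 0x1 paired, 0x2 properly paired, 0x4 unmapped, 0x40/0x80 mate
#'   index are honored, MAPQ is taken as printed, CIGAR must be a single
#'   `<n>M` match for mapped mates). Coordinates convert from SAM's 1-based
#'   to the internal 0-based convention at this boundary.
#'
#' @param path Input file.
#' @param dialect `"truth_tsv"` or `"sam_subset"`.
#' @param genome_lengths Optional named length vector; when supplied, mapped
#'   coordinates are bound-checked and violations raise a parse error naming
#'   the line.
#' @return Pair-level `data.frame` in the [generate_reads()] column layout.
#' @export
read_alignments <- function(path, dialect = c("truth_tsv", "sam_subset"),
                            genome_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_argument(paste("no such file:", path))
  records <- switch(dialect,
                    truth_tsv = read_truth_tsv(path),
                    sam_subset = read_sam_subset(path))
  if (!is.null(genome_lengths) && nrow(records)) {
    lens <- genome_lengths(genome_lengths)
    check_mate <- function(gid, start, mate) {
      bad <- which(records$is_mapped & !is.na(start) &
                     (start < 0 | start + records$read_length > lens[gid]))
      if (length(bad))
        stop_parse(sprintf("mate %d of pair %s out of bounds for genome %s",
                           mate, records$pair_id[bad[1]], gid[bad[1]]))
    }
    check_mate(records$genome_id, records$mate1_start, 1L)
    check_mate(records$mate2_genome_id, records$mate2_start, 2L)
  }
  records
}

read_truth_tsv <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(pair_id = "integer", genome_id = "character",
                              mate2_genome_id = "character",
                              mate1_start = "integer", mate2_start = "integer",
                              read_length = "integer", insert_size = "integer",
                              paired = "logical", is_mapped = "logical",
                              is_proper = "logical", is_chimera = "logical",
                              mapq = "integer")),
    error = function(e) stop_parse(paste("malformed truth TSV:",
                                         conditionMessage(e))))
  need <- names(empty_read_pairs())
  if (!all(need %in% names(df)))
    stop_parse(paste("truth TSV missing columns:",
                     paste(setdiff(need, names(df)), collapse = ", ")))
  df[, need]
}

read_sam_subset <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (!length(body_idx)) return(empty_read_pairs())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop_parse(sprintf("line %d: expected >= 9 SAM columns, found %d",
                       body_idx[which(nf < 9)[1]], min(nf)))
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq))
    stop_parse(sprintf("line %d: non-numeric FLAG, POS or MAPQ",
                       body_idx[which(is.na(flag) | is.na(pos) | is.na(mapq))[1]]))
  rname <- vapply(fields, `[[`, "", 3L)
  cigar <- vapply(fields, `[[`, "", 6L)
  mapped <- bitwAnd(flag, 4L) == 0L
  rl <- rep(NA_integer_, length(flag))
  cig_ok <- grepl("^[0-9]+M$", cigar)
  rl[cig_ok] <- as.integer(sub("M$", "", cigar[cig_ok]))
  bad_cig <- mapped & !cig_ok
  if (any(bad_cig))
    stop_parse(sprintf("line %d: unsupported CIGAR '%s' (only <n>M handled)",
                       body_idx[which(bad_cig)[1]], cigar[which(bad_cig)[1]]))
  first <- bitwAnd(flag, 64L) != 0L
  ord <- order(match(qname, unique(qname)), !first)
  # regroup lines into pairs by query name
  grp <- split(seq_along(qname)[ord], factor(qname[ord], levels = unique(qname)))
  rows <- lapply(seq_along(grp), function(k) {
    idx <- grp[[k]]
    i1 <- idx[which(first[idx])[1]]
    i2 <- idx[which(!first[idx])[1]]
    if (is.na(i1)) { i1 <- i2; i2 <- NA_integer_ }  # singleton second mate
    m2_present <- !is.na(i2)
    prop <- bitwAnd(flag[i1], 2L) != 0L && mapped[i1]
    data.frame(pair_id = k,
               genome_id = if (mapped[i1]) rname[i1] else "artifact",
               mate2_genome_id = if (m2_present && mapped[i2]) rname[i2]
                                 else if (mapped[i1]) rname[i1] else "artifact",
               mate1_start = if (mapped[i1]) pos[i1] - 1L else NA_integer_,
               mate2_start = if (m2_present && mapped[i2]) pos[i2] - 1L
                             else NA_integer_,
               read_length = if (mapped[i1]) rl[i1]
                             else if (m2_present && mapped[i2]) rl[i2]
                             else NA_integer_,
               insert_size = NA_integer_,
               paired = bitwAnd(flag[i1], 1L) != 0L && m2_present,
               is_mapped = mapped[i1] || (m2_present && mapped[i2]),
               is_proper = prop,
               is_chimera = FALSE,
               mapq = mapq[i1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # recover insert size for proper pairs from TLEN of the first mate
  tlen <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 9L)))
  first_line_of_pair <- vapply(grp, function(idx) {
    i1 <- idx[which(first[idx])[1]]
    if (is.na(i1)) idx[1] else i1
  }, integer(1))
  out$insert_size <- ifelse(out$is_proper, abs(tlen[first_line_of_pair]),
                            NA_integer_)
  out$is_chimera <- out$is_mapped & !out$is_proper
  rownames(out) <- NULL
  out
}

#' Per-position depth from alignment records
#'
#' Every mapped mate increments depth over `[start, start + read_length)`;
#' overlapping mates of one pair double-count the overlap, matching the
#' per-base semantics of standard depth tools. Total depth therefore equals
#' `2 * read_length * n_pairs` when both mates of every pair map to the
#' genome.
#'
#' @param records Pair-level alignment `data.frame`.
#' @param genome_length Genome length in bp.
#' @param read_length Read length in bp (all mates fixed length).
#' @param genome_id Genome to pile up on; may be omitted when the mapped
#'   records name a single genome.
#' @return A [depth_vector()].
#' @export
depth_from_alignments <- function(records, genome_length, read_length,
                                  genome_id = NULL) {
  mapped_g <- unique(c(records$genome_id[records$is_mapped],
                       records$mate2_genome_id[records$is_mapped]))
  mapped_g <- setdiff(mapped_g, "artifact")
  if (is.null(genome_id)) {
    if (length(mapped_g) > 1)
      stop_argument("records map to several genomes; pass `genome_id`")
    genome_id <- if (length(mapped_g)) mapped_g else NA_character_
  }
  starts <- c(records$mate1_start[records$is_mapped &
                                    records$genome_id == genome_id],
              records$mate2_start[records$is_mapped &
                                    records$mate2_genome_id == genome_id])
  starts <- starts[!is.na(starts)]
  if (length(starts) && (min(starts) < 0 ||
                         max(starts) + read_length > genome_length))
    stop_argument("a mate extends past the genome end")
  delta <- tabulate(starts + 1L, nbins = genome_length + 1L) -
    tabulate(starts + read_length + 1L, nbins = genome_length + 1L)
  depth_vector(genome_id, cumsum(delta)[seq_len(genome_length)])
}

#' Read a samtools-depth style TSV into dense depth vectors
#'
#' Three columns (genome, 1-based position, depth), no header; positions
#' absent from the file are zero (the sparse default dialect of
#' `samtools depth`). Every genome declared in `genome_lengths` yields one
#' dense vector, all-zero if the file never mentions it.
#'
#' @param path Input TSV.
#' @param genome_lengths Named vector of genome lengths (or `DNAStringSet`).
#' @return Named list of [depth_vector()], one per declared genome.
#' @export
read_depth_tsv <- function(path, genome_lengths) {
  lens <- genome_lengths(genome_lengths)
  out <- lapply(names(lens), function(g) depth_vector(g, numeric(lens[g])))
  names(out) <- names(lens)
  if (!file.exists(path)) stop_argument(paste("no such file:", path))
  if (file.size(path) == 0) return(out)
  df <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                            col.names = c("genome", "pos", "depth"),
                            colClasses = c("character", "integer", "numeric")),
                 error = function(e) stop_parse(paste("malformed depth TSV:",
                                                      conditionMessage(e))))
  unknown <- setdiff(unique(df$genome), names(lens))
  if (length(unknown))
    stop_parse(paste("depth TSV names undeclared genome:", unknown[1]))
  for (g in unique(df$genome)) {
    sub <- df[df$genome == g, ]
    if (any(sub$pos < 1 | sub$pos > lens[g]))
      stop_parse(sprintf("depth TSV position outside genome %s (length %d)",
                         g, lens[g]))
    out[[g]]$depth[sub$pos] <- sub$depth
  }
  out
}

#' Write depth vectors as a samtools-depth style TSV
#'
#' @param depths A [depth_vector()] or list of them.
#' @param path Output file.
#' @param include_zeros Write zero-depth positions too (default `FALSE`,
#'   the sparse dialect).
#' @export
write_depth_tsv <- function(depths, path, include_zeros = FALSE) {
  if (inherits(depths, "depth_vector")) depths <- list(depths)
  rows <- lapply(depths, function(d) {
    keep <- if (include_zeros) seq_along(d$depth) else which(d$depth > 0)
    data.frame(genome = d$genome_id, pos = keep, depth = d$depth[keep])
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genome lengths from a FASTA file or a two-column TSV
#'
#' @param path FASTA (detected by a leading `>`) or headerless TSV of
#'   (genome_id, length).
#' @return Named integer vector of lengths.
#' @export
read_genome_lengths <- function(path) {
  if (!file.exists(path)) stop_argument(paste("no such file:", path))
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(genome_lengths(seqs))
  }
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("genome", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$genome)
}

#' Coverage breadth
#'
#' Percentage of genome positions covered at least `min_depth` times — the
#' "percentage of the genome covered at least 1x" of a coverage report.
#'
#' @param depth A [depth_vector()].
#' @param min_depth Depth threshold (>= 1).
#' @return Percentage in `[0, 100]`.
#' @examples
#' breadth(depth_vector("g", c(0, 2, 0, 5)))        # 50
#' breadth(depth_vector("g", c(0, 2, 0, 5)), 3)     # 25
#' @export
breadth <- function(depth, min_depth = 1) {
  stopifnot(inherits(depth, "depth_vector"))
  if (min_depth < 1) stop_argument("`min_depth` must be >= 1")
  100 * mean(depth$depth >= min_depth)
}

#' Read-mapping statistics for a sample
#'
#' Pair-level flagstat-style accounting: the fraction of pairs that map to
#' any member genome, and — among mapped pairs — the fraction that are
#' properly paired (both mates on one genome at the expected orientation and
#' distance; its complement proxies chimeric amplification artifacts).
#'
#' @param records Pair-level alignment `data.frame`.
#' @return A list of class `mapping_stats`: `total_pairs`, `mapped_pairs`,
#'   `proper_pairs`, `mapped_fraction` and `properly_paired_fraction`
#'   (percent; `NA` when the denominator is empty).
#' @export
mapping_stats <- function(records) {
  total <- nrow(records)
  mapped <- sum(records$is_mapped)
  proper <- sum(records$is_proper)
  structure(list(total_pairs = total,
                 mapped_pairs = mapped,
                 proper_pairs = proper,
                 mapped_fraction = if (total) 100 * mapped / total else NA_real_,
                 properly_paired_fraction = if (mapped) 100 * proper / mapped
                                            else NA_real_),
            class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("<mapping_stats> %d pairs: %.2f%% mapped, %.2f%% properly paired (of mapped)\n",
              x$total_pairs, x$mapped_fraction, x$properly_paired_fraction))
  invisible(x)
}
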