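test_that("depth piles up mate intervals and conserves placed bases", {
  expect_equal(depth_from_alignments(make_pairs(0), 20, 5, "g")$depth,
               rep(0, 20))

  d <- depth_from_alignments(make_pairs(1), 20, 5, "g")
  expect_equal(d$depth, c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5)))

  sim <- simulate_single_genome_reads(1000, seed = 51)
  d <- depth_from_alignments(sim$records, 20000, 100, "g")
  expect_equal(sum(d$depth), 2 * 1000 * 100)

  bad <- make_pairs(1, mate2_start = 18L)
  expect_error(depth_from_alignments(bad, 20, 5, "g"),
               class = "dropmda_argument_error")
})

test_that("depth TSV round-trips through the sparse samtools dialect", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("g\t1\t5", "g\t3\t2"), tsv)
  d <- read_depth_tsv(tsv, c(g = 4L))
  expect_equal(d$g$depth, c(5, 0, 2, 0))

  file.create(empty <- tempfile(fileext = ".tsv"))
  expect_equal(read_depth_tsv(empty, c(g = 10L))$g$depth, rep(0, 10))

  set.seed(1)
  dv <- depth_vector("g", rpois(200, 1))
  write_depth_tsv(dv, tsv)
  expect_equal(read_depth_tsv(tsv, c(g = 200L))$g, dv)
  write_depth_tsv(dv, tsv, include_zeros = TRUE)
  expect_equal(read_depth_tsv(tsv, c(g = 200L))$g, dv)

  writeLines("g\t7\t1", tsv)
  expect_error(read_depth_tsv(tsv, c(g = 4L)), class = "dropmda_parse_error")
  writeLines("h\t1\t1", tsv)
  expect_error(read_depth_tsv(tsv, c(g = 4L)), class = "dropmda_parse_error")
})

test_that("truth TSV round-trip is the identity on simulated records", {
  sim <- simulate_single_genome_reads(100, seed = 61, chimera_rate = 0.1,
                                      contamination_rate = 0.1,
                                      multimap_rate = 0.1)
  path <- tempfile(fileext = ".tsv")
  write_truth_tsv(sim$records, path)
  back <- read_alignments(path, "truth_tsv")
  expect_equal(back, sim$records)
})

test_that("SAM subset round-trips the alignment facts", {
  sim <- simulate_single_genome_reads(100, seed = 71, chimera_rate = 0.1,
                                      contamination_rate = 0.05,
                                      multimap_rate = 0.1)
  lens <- genome_lengths(sim$genomes)
  path <- tempfile(fileext = ".sam")
  write_sam(sim$records, path, lens)
  back <- read_alignments(path, "sam_subset", genome_lengths = lens)
  for (col in c("genome_id", "mate2_genome_id", "mate1_start", "mate2_start",
                "is_mapped", "is_proper", "is_chimera", "mapq"))
    expect_equal(back[[col]], sim$records[[col]], label = col)
})

test_that("SAM reader honors flags, reports malformed lines and bounds", {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:g\tLN:100")
  pair <- function(mapq) c(
    sprintf("p1\t99\tg\t11\t%d\t10M\t=\t31\t30\tNNNNNNNNNN\t*", mapq),
    sprintf("p1\t147\tg\t31\t%d\t10M\t=\t11\t-30\tNNNNNNNNNN\t*", mapq))
  writeLines(c(hdr, pair(0L)), path)
  rec <- read_alignments(path, "sam_subset")
  expect_true(rec$is_proper)       # FLAG 99 keeps proper pairing even at MAPQ 0
  expect_equal(rec$mapq, 0L)
  expect_equal(rec$mate1_start, 10L)
  expect_equal(rec$insert_size, 30L)

  writeLines(c(hdr, "p1\t99\tg\t11\t60\t10M\t=\t31"), path)
  expect_error(read_alignments(path, "sam_subset"), "line 3",
               class = "dropmda_parse_error")

  writeLines(c(hdr, pair(60L)[1], sub("\t31\t", "\t95\t", pair(60L)[2])), path)
  expect_error(read_alignments(path, "sam_subset", genome_lengths = c(g = 100L)),
               class = "dropmda_parse_error")

  file.create(empty <- tempfile(fileext = ".sam"))
  expect_equal(nrow(read_alignments(empty, "sam_subset")), 0)
})

test_that("breadth counts thresholded positions and is monotone", {
  d <- depth_vector("g", c(0, 2, 0, 5))
  expect_equal(breadth(d), 50)
  expect_equal(breadth(d, 3), 25)
  expect_equal(breadth(depth_vector("g", rep(0, 7))), 0)
  set.seed(2)
  dv <- depth_vector("g", rpois(300, 2))
  b <- vapply(1:6, function(k) breadth(dv, k), numeric(1))
  expect_true(all(diff(b) <= 0))
})

test_that("mapping statistics use pair-level flagstat semantics", {
  ms <- mapping_stats(make_pairs(100))
  expect_equal(ms$mapped_fraction, 100)
  expect_equal(ms$properly_paired_fraction, 100)

  rec <- rbind(make_pairs(95), make_pairs(5, is_proper = FALSE,
                                          is_chimera = TRUE))
  expect_equal(mapping_stats(rec)$properly_paired_fraction, 95)

  empty <- mapping_stats(make_pairs(0))
  expect_true(is.na(empty$mapped_fraction))
  expect_true(is.na(empty$properly_paired_fraction))

  sim <- simulate_single_genome_reads(1e5, chimera_rate = 0.05, seed = 81)
  pp <- mapping_stats(sim$records)$properly_paired_fraction
  expect_lt(abs(pp - 95), 300 * sqrt(0.05 * 0.95 / 1e5))
})

test_that("genome lengths load from FASTA and from TSV", {
  g <- generate_mock_genomes(2, c(1200, 1500), c(0.5, 0.5), seed = 91)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(g, fa)
  expect_equal(read_genome_lengths(fa), c(genome_1 = 1200L, genome_2 = 1500L))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("a\t100", "b\t250"), tsv)
  expect_equal(read_genome_lengths(tsv), c(a = 100L, b = 250L))
})
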