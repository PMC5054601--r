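ARMS <- c("unamplified", "emulsion", "bulk")

#' Default experiment configuration
#'
#' Desk-scale defaults for the three-arm comparison (unamplified control,
#' MDA in emulsion, MDA in bulk) of a five-member mock community: 50-kb
#' genomes mixed at a 0.45/0.30/0.15/0.07/0.03 mass staircase, 10-pl
#' droplets emulsifying 0.2 ul of reaction (2e4 droplets), mean occupancy
#' `lambda = 0.2` templates per droplet, lognormal gain shape 2, median
#' fold-gain 2000, per-droplet copy budget 400, and per-arm library sizes,
#' chimera and contamination rates chosen so the unamplified arm shows >99%
#' properly paired reads and the amplified arms ~95%, as real mock-community
#' libraries do. Genomes and template numbers are scaled down together
#' (about 100x below the physical experiment) so that per-position template
#' redundancy — the quantity that decides how strongly per-template gain
#' dispersion shows up in coverage depth — stays in the low-input regime the
#' method targets; see the package vignette for the scaling argument. All
#' values can be overridden; `reaction_capacity = NULL` means the bulk arm
#' gets the same total copy budget as the emulsion arm
#' (`droplet_count * droplet_capacity`), making the comparison paired.
#'
#' @return Named list of parameters accepted by [run_experiment()].
#' @export
default_config <- function() {
  list(
    n_genomes = 5L,
    genome_length = 50000L,
    gc = c(0.60, 0.54, 0.62, 0.58, 0.66),
    mass_fractions = c(0.45, 0.30, 0.15, 0.07, 0.03),
    droplet_volume_pl = 10,
    reaction_volume_ul = 0.2,
    lambda = 0.2,
    fragment_length_mean = 500L,
    gain_sigma = 2,
    gain_scale = 2000,
    droplet_capacity = 400L,
    reaction_capacity = NULL,
    read_length = 150L,
    insert_mean = 300L,
    insert_sd = 20,
    n_pairs = c(unamplified = 24000L, emulsion = 22000L, bulk = 20000L),
    chimera_rate = c(unamplified = 0.007, emulsion = 0.05, bulk = 0.05),
    contamination_rate = c(unamplified = 0.004, emulsion = 0.02, bulk = 0.02),
    multimap_rate = 0.02,
    target_depth = 5.0
  )
}

#' Read an experiment configuration from YAML
#'
#' Keys present in the file override [default_config()]; per-arm keys
#' (`n_pairs`, `chimera_rate`, `contamination_rate`) may be scalars (applied
#' to every arm) or maps keyed by arm name.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  for (k in c("n_pairs", "chimera_rate", "contamination_rate")) {
    v <- unlist(cfg[[k]])
    if (length(v) == 1L && is.null(names(v))) v <- setNames(rep(v, 3), ARMS)
    cfg[[k]] <- v[ARMS]
  }
  cfg
}

per_arm <- function(x, arm) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && arm %in% names(x)) return(unname(x[[arm]]))
  stop_argument(sprintf("per-arm parameter lacks a value for arm '%s'", arm))
}

#' Species-abundance table from proper pairs
#'
#' Counts properly paired reads per member genome in each sample; the
#' recovered proportion of each species is its proper-pair share of all
#' genome-mapped proper pairs (artifact reads are excluded from the
#' denominator and reported in the `artifact_pairs` attribute). This is the
#' read-based estimate of the community's species distribution.
#'
#' @param samples List of [sample_read_set()] objects.
#' @param genome_ids Optional character vector fixing the genome rows (and
#'   their order) for every sample; genomes without proper pairs get a zero
#'   row. Defaults to the genomes observed per sample.
#' @return `data.frame` with columns `sample_id`, `genome_id`,
#'   `proper_pairs`, `proportion`; per-sample proportions sum to 1 (when any
#'   proper pairs exist).
#' @export
abundance_table <- function(samples, genome_ids = NULL) {
  stopifnot(all(vapply(samples, inherits, TRUE, "sample_read_set")))
  artifact <- integer(0)
  rows <- lapply(samples, function(s) {
    rec <- s$records
    proper <- rec[rec$is_proper, , drop = FALSE]
    gids <- if (is.null(genome_ids)) sort(unique(proper$genome_id)) else genome_ids
    counts <- setNames(integer(length(gids)), gids)
    tab <- table(proper$genome_id)
    counts[names(tab)[names(tab) %in% gids]] <-
      as.integer(tab[names(tab) %in% gids])
    artifact[s$sample_id] <<- sum(!rec$is_mapped)
    if (!length(gids)) {
      return(data.frame(sample_id = character(0), genome_id = character(0),
                        proper_pairs = integer(0), proportion = numeric(0)))
    }
    data.frame(sample_id = s$sample_id, genome_id = gids,
               proper_pairs = unname(counts),
               proportion = if (sum(counts)) unname(counts) / sum(counts)
                            else rep(NA_real_, length(counts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "artifact_pairs") <- artifact
  out
}

simulate_arm_reads <- function(cfg, arm, amp, templates, genomes) {
  generate_reads(amp, templates, genomes,
                 n_pairs = per_arm(cfg$n_pairs, arm),
                 read_length = cfg$read_length,
                 insert_mean = cfg$insert_mean,
                 insert_sd = cfg$insert_sd,
                 chimera_rate = per_arm(cfg$chimera_rate, arm),
                 contamination_rate = per_arm(cfg$contamination_rate, arm),
                 multimap_rate = per_arm(cfg$multimap_rate, arm))
}

#' Run the three-arm amplification-uniformity experiment
#'
#' One replicate of the full analysis: a mock community is fragmented into
#' one template pool shared by all three arms (so arm differences are purely
#' the amplification model), amplified as unamplified control / emulsion /
#' bulk, sequenced in silico, and pushed through the comparison pipeline —
#' mapping statistics on the raw libraries; unpaired- and multi-mapper
#' filtering; equal-data subsampling for the abundance table and per-genome
#' coverage breadth; per-genome subsampling to `target_depth`x mean coverage
#' for breadth/CV/Gini uniformity statistics. Genomes for which a sample
#' holds too few proper pairs for the coverage target are reported as
#' unavailable rather than failing the run.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Optional master seed; one seed determines every random draw,
#'   so reruns are byte-identical.
#' @return An object of class `sample_report`: list with `mapping`,
#'   `abundance`, `breadth_equal_data`, `uniformity` data frames, the truth
#'   `community`, and a `manifest` (config, seed, package version).
#' @export
run_experiment <- function(config = default_config(), seed = NULL) {
  cfg <- config
  droplet_count <- floor(cfg$reaction_volume_ul * 1e6 / cfg$droplet_volume_pl)
  reaction_capacity <- if (is.null(cfg$reaction_capacity))
    droplet_count * cfg$droplet_capacity else cfg$reaction_capacity
  with_seed(seed, {
    genomes <- generate_mock_genomes(cfg$n_genomes,
                                     rep(cfg$genome_length, cfg$n_genomes),
                                     cfg$gc)
    lens <- genome_lengths(genomes)
    community <- mock_community(names(genomes), cfg$mass_fractions)
    n_templates <- max(1L, as.integer(round(cfg$lambda * droplet_count)))
    templates <- fragment_templates(community, genomes, n_templates,
                                    cfg$fragment_length_mean)
    partition <- partition_into_droplets(templates, cfg$droplet_volume_pl,
                                         cfg$reaction_volume_ul)
    amps <- list(
      unamplified = amplify_none(templates),
      emulsion = amplify_emulsion(templates, partition, cfg$gain_sigma,
                                  cfg$droplet_capacity,
                                  gain_scale = cfg$gain_scale),
      bulk = amplify_bulk(templates, cfg$gain_sigma, reaction_capacity,
                          gain_scale = cfg$gain_scale))
    reads <- lapply(setNames(ARMS, ARMS), function(arm)
      simulate_arm_reads(cfg, arm, amps[[arm]], templates, genomes))

    mapping <- do.call(rbind, lapply(ARMS, function(arm) {
      ms <- mapping_stats(reads[[arm]])
      data.frame(sample_id = arm, total_pairs = ms$total_pairs,
                 mapped_fraction = ms$mapped_fraction,
                 properly_paired_fraction = ms$properly_paired_fraction)
    }))

    filtered <- lapply(reads, function(r) filter_multimapped(filter_unpaired(r)))
    equalized <- equal_data_subsample(
      lapply(ARMS, function(arm)
        sample_read_set(arm, filtered[[arm]], cfg$read_length)))
    names(equalized) <- ARMS

    abundance <- abundance_table(equalized, genome_ids = names(lens))

    breadth_eq <- do.call(rbind, lapply(ARMS, function(arm) {
      rec <- equalized[[arm]]$records
      data.frame(sample_id = arm, genome_id = names(lens),
                 breadth_percent = vapply(names(lens), function(g)
                   breadth(depth_from_alignments(rec, lens[[g]],
                                                 cfg$read_length, g)),
                   numeric(1)),
                 stringsAsFactors = FALSE)
    }))

    uniformity <- do.call(rbind, lapply(ARMS, function(arm) {
      rec <- filtered[[arm]]
      do.call(rbind, lapply(names(lens), function(g) {
        sel <- rec[rec$is_proper & rec$genome_id == g, , drop = FALSE]
        res <- tryCatch({
          sub <- target_coverage_subsample(sel, lens[[g]], cfg$read_length,
                                           cfg$target_depth)
          ur <- uniformity_report(
            depth_from_alignments(sub, lens[[g]], cfg$read_length, g))
          data.frame(sample_id = arm, genome_id = g, available = TRUE,
                     breadth_percent = ur$breadth_percent,
                     cv_percent = ur$cv_percent, gini = ur$gini,
                     stringsAsFactors = FALSE)
        }, dropmda_insufficient_pairs = function(e) {
          data.frame(sample_id = arm, genome_id = g, available = FALSE,
                     breadth_percent = NA_real_, cv_percent = NA_real_,
                     gini = NA_real_, stringsAsFactors = FALSE)
        })
        res
      }))
    }))
    rownames(breadth_eq) <- rownames(uniformity) <- NULL

    structure(list(mapping = mapping,
                   abundance = abundance,
                   breadth_equal_data = breadth_eq,
                   uniformity = uniformity,
                   community = community,
                   yields = data.frame(
                     sample_id = ARMS,
                     yield_au = vapply(amps, `[[`, numeric(1), "yield_au")),
                   manifest = list(config = cfg, seed = seed,
                                   droplet_count = droplet_count,
                                   reaction_capacity = reaction_capacity,
                                   n_templates = n_templates,
                                   package = "dropmda",
                                   version = as.character(packageVersion("dropmda")))),
              class = "sample_report")
  })
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report> three-arm amplification-uniformity experiment\n")
  cat(sprintf("  community: %d genomes, fractions %s\n",
              nrow(x$community),
              paste(format(x$community$mass_fraction), collapse = "/")))
  cat("  mapping:\n")
  print(x$mapping, row.names = FALSE)
  cat("  per-genome uniformity at target coverage:\n")
  print(x$uniformity, row.names = FALSE)
  invisible(x)
}

#' Run replicate experiments from one master seed
#'
#' @param config Configuration list.
#' @param n_replicates Number of independent replicates.
#' @param seed Master seed; each replicate gets a derived child seed.
#' @return List of [run_experiment()] reports.
#' @export
replicate_experiment <- function(config = default_config(), n_replicates,
                                 seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", n_replicates)
           else as.list(derive_seeds(seed, n_replicates))
  lapply(seq_len(n_replicates), function(i)
    run_experiment(config, seed = seeds[[i]]))
}

#' Per-replicate trend metrics from a set of reports
#'
#' Distills replicate reports into the comparisons the three-arm experiment
#' is about: per arm, the L1 distance between recovered and true species
#' proportions, the rarest member's recovered proportion and equal-data
#' breadth, and the per-genome uniformity statistics.
#'
#' @param reports List of `sample_report` objects.
#' @return List of two data frames: `abundance` (replicate, sample_id, l1,
#'   rare_proportion, rare_breadth) and `uniformity` (replicate, sample_id,
#'   genome_id, available, breadth_percent, cv_percent, gini).
#' @export
summarize_replicates <- function(reports) {
  stopifnot(all(vapply(reports, inherits, TRUE, "sample_report")))
  ab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rep_i <- reports[[i]]
    truth <- setNames(rep_i$community$mass_fraction, rep_i$community$genome_id)
    rare <- names(truth)[which.min(truth)]
    do.call(rbind, lapply(unique(rep_i$abundance$sample_id), function(arm) {
      sub <- rep_i$abundance[rep_i$abundance$sample_id == arm, ]
      prop <- setNames(sub$proportion, sub$genome_id)[names(truth)]
      prop[is.na(prop)] <- 0
      brd <- rep_i$breadth_equal_data
      data.frame(replicate = i, sample_id = arm,
                 l1 = sum(abs(prop - truth)),
                 rare_proportion = prop[[rare]],
                 rare_breadth = brd$breadth_percent[brd$sample_id == arm &
                                                      brd$genome_id == rare],
                 stringsAsFactors = FALSE)
    }))
  }))
  un <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(replicate = i, reports[[i]]$uniformity)))
  rownames(ab) <- rownames(un) <- NULL
  list(abundance = ab, uniformity = un)
}

#' Write a sample report to disk
#'
#' Emits the report tables as TSV files plus a YAML manifest carrying the
#' full configuration and master seed, from which every number in the report
#' can be regenerated.
#'
#' @param report A `sample_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sample_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("mapping", "abundance", "breadth_equal_data", "uniformity", "yields")
  for (tb in tabs)
    write.table(report[[tb]], file.path(dir, paste0(tb, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- report$manifest
  manifest$config <- lapply(manifest$config, function(v)
    if (is.null(v)) NULL else as.vector(v))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
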