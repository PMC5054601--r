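#' Partition template molecules into emulsion droplets
#'
#' Models loading of denatured template molecules into a monodisperse emulsion:
#' each template lands in a uniformly random droplet, so droplet occupancy
#' counts are Poisson with mean `lambda = n_templates / droplet_count`. The
#' droplet count follows from the emulsified reaction volume and the droplet
#' volume (a 10 pl droplet is ~26 um in diameter).
#'
#' @param templates Template `data.frame` from [fragment_templates()].
#' @param droplet_volume_pl Droplet volume in picoliters (> 0).
#' @param reaction_volume_ul Emulsified reaction volume in microliters (> 0).
#' @param seed Optional integer seed.
#' @return An object of class `droplet_partition`: a list with
#'   `droplet_count`, `assignment` (integer droplet index in
#'   `1..droplet_count`, parallel to `templates`), `template_id`, and
#'   `occupancy_lambda`.
#' @examples
#' comm <- mock_community("g", 1)
#' tpl <- fragment_templates(comm, c(g = 50000L), 100, 2000, seed = 1)
#' part <- partition_into_droplets(tpl, 10, 0.01, seed = 1)
#' part$occupancy_lambda
#' @export
partition_into_droplets <- function(templates, droplet_volume_pl,
                                    reaction_volume_ul, seed = NULL) {
  if (droplet_volume_pl <= 0 || reaction_volume_ul <= 0)
    stop_argument("droplet and reaction volumes must be > 0")
  droplet_count <- floor(reaction_volume_ul * 1e6 / droplet_volume_pl)
  if (droplet_count < 1)
    stop_argument("reaction volume smaller than one droplet")
  n <- nrow(templates)
  assignment <- with_seed(seed, {
    if (n == 0) integer(0) else sample.int(droplet_count, n, replace = TRUE)
  })
  structure(list(droplet_count = droplet_count,
                 assignment = assignment,
                 template_id = templates$template_id,
                 occupancy_lambda = n / droplet_count),
            class = "droplet_partition")
}

#' Droplet occupancy counts
#'
#' @param partition A [partition_into_droplets()] result.
#' @return Integer vector of length `droplet_count`: templates per droplet.
#' @export
droplet_occupancy <- function(partition) {
  stopifnot(inherits(partition, "droplet_partition"))
  tabulate(partition$assignment, nbins = partition$droplet_count)
}

new_amplification_result <- function(template_id, copies, mode, yield_au) {
  structure(list(template_id = template_id,
                 copies = as.numeric(copies),
                 mode = mode,
                 yield_au = yield_au),
            class = "amplification_result")
}

# Heavy-tailed per-template raw gains: gain_scale * lognormal(0, gain_sigma).
# The lognormal has unit median; gain_scale sets the fold-amplification an
# uninhibited template achieves (MDA routinely amplifies thousands-fold).
raw_gains <- function(n, gain_sigma, gain_scale) {
  if (gain_sigma < 0) stop_argument("`gain_sigma` must be >= 0")
  if (gain_scale <= 0) stop_argument("`gain_scale` must be > 0")
  gain_scale * rlnorm(n, meanlog = 0, sdlog = gain_sigma)
}

#' Simulate bulk MDA with global competition
#'
#' Every template draws a raw amplification gain from a heavy-tailed
#' lognormal; when the summed raw copies exceed the reaction capacity, the
#' fixed copy budget is allocated by a multinomial draw with probabilities
#' proportional to the raw gains. Fast-amplifying templates thereby inhibit
#' the rest — the winner-take-most behavior that skews bulk MDA of mixed
#' samples. When capacity does not bind, copies are the rounded raw gains.
#'
#' @param templates Template `data.frame`.
#' @param gain_sigma Lognormal shape of the per-template gain (>= 0); larger
#'   values give heavier-tailed, more biased amplification.
#' @param reaction_capacity Total copy budget of the reaction; must be at
#'   least the number of templates.
#' @param seed Optional integer seed.
#' @param gain_scale Median fold-gain of an uninhibited template (default 2000).
#' @return An `amplification_result` with `mode = "bulk"`, integer-valued
#'   `copies` per template, and `yield_au` = sum of copies times template
#'   length (arbitrary mass units).
#' @export
amplify_bulk <- function(templates, gain_sigma, reaction_capacity, seed = NULL,
                         gain_scale = 2000) {
  n <- nrow(templates)
  if (reaction_capacity < n)
    stop_argument("`reaction_capacity` must be >= number of templates")
  with_seed(seed, {
    w <- raw_gains(n, gain_sigma, gain_scale)
    copies <- if (n == 0) {
      numeric(0)
    } else if (sum(w) > reaction_capacity) {
      as.numeric(rmultinom(1, reaction_capacity, w))
    } else round(w)
    new_amplification_result(templates$template_id, copies, "bulk",
                             sum(copies * templates$length))
  })
}

#' Simulate emulsion (droplet-partitioned) MDA
#'
#' As [amplify_bulk()], but competition and capacity apply per droplet: each
#' droplet is an isolated reaction chamber with its own copy budget
#' `droplet_capacity`. A template alone in its droplet saturates at
#' `droplet_capacity` whenever its raw gain exceeds it, so at low occupancy
#' most templates reach the same final copy number regardless of their gain —
#' the mechanism by which partitioning evens out amplification.
#'
#' @param templates Template `data.frame`.
#' @param partition Matching [partition_into_droplets()] result.
#' @param gain_sigma Lognormal gain shape (>= 0).
#' @param droplet_capacity Copy budget per droplet (>= 1).
#' @param seed Optional integer seed.
#' @param gain_scale Median fold-gain of an uninhibited template (default 2000).
#' @return An `amplification_result` with `mode = "emulsion"`.
#' @export
amplify_emulsion <- function(templates, partition, gain_sigma, droplet_capacity,
                             seed = NULL, gain_scale = 2000) {
  if (!inherits(partition, "droplet_partition"))
    stop_argument("`partition` must come from partition_into_droplets()")
  if (droplet_capacity < 1) stop_argument("`droplet_capacity` must be >= 1")
  if (!identical(as.integer(partition$template_id),
                 as.integer(templates$template_id)))
    stop(errorCondition("partition and templates disagree on template ids",
                        class = c("dropmda_consistency_error", "error", "condition")))
  n <- nrow(templates)
  with_seed(seed, {
    w <- raw_gains(n, gain_sigma, gain_scale)
    copies <- numeric(n)
    if (n > 0) {
      occ <- tabulate(partition$assignment, nbins = partition$droplet_count)
      alone <- occ[partition$assignment] == 1L
      copies[alone] <- pmin(round(w[alone]), droplet_capacity)
      shared <- which(!alone)
      if (length(shared)) {
        groups <- split(shared, partition$assignment[shared])
        for (idx in groups) {
          wi <- w[idx]
          copies[idx] <- if (sum(wi) > droplet_capacity) {
            as.numeric(rmultinom(1, droplet_capacity, wi))
          } else round(wi)
        }
      }
    }
    new_amplification_result(templates$template_id, copies, "emulsion",
                             sum(copies * templates$length))
  })
}

#' Unamplified control
#'
#' Every template is present in exactly one copy; the unamplified sample is
#' the ground truth the amplified arms are judged against.
#'
#' @param templates Template `data.frame`.
#' @return An `amplification_result` with `mode = "unamplified"` and all
#'   copies equal to 1.
#' @export
amplify_none <- function(templates) {
  new_amplification_result(templates$template_id,
                           rep(1, nrow(templates)), "unamplified",
                           sum(templates$length))
}

#' Simulated amplification yield across input concentrations
#'
#' Reproduces, in arbitrary units, the qualitative yield-versus-input trend:
#' bulk reactions are capacity-limited and yield roughly the same mass no
#' matter how little template goes in, while emulsion yield tracks the
#' fraction of droplets that received at least one template, `1 - exp(-lambda)`,
#' and therefore drops once the mean occupancy falls below one molecule per
#' droplet.
#'
#' @param lambdas Mean templates per droplet (> 0), one value per condition.
#' @param mode `"bulk"` or `"emulsion"`.
#' @param droplet_count Number of droplets the reaction volume partitions into.
#' @param droplet_capacity Copy budget per droplet.
#' @param gain_sigma,gain_scale Gain distribution parameters.
#' @param fragment_length Template length in bp (fixed across conditions).
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `lambda`, `mode`, `yield_au`.
#' @export
simulate_yield_curve <- function(lambdas, mode = c("bulk", "emulsion"),
                                 droplet_count = 1e5, droplet_capacity = 400,
                                 gain_sigma = 2, gain_scale = 2000,
                                 fragment_length = 500, seed = NULL) {
  mode <- match.arg(mode)
  if (any(lambdas <= 0)) stop_argument("`lambdas` must be > 0")
  with_seed(seed, {
    yields <- vapply(lambdas, function(lam) {
      n <- max(1L, as.integer(round(lam * droplet_count)))
      tpl <- data.frame(template_id = seq_len(n), genome_id = "pool",
                        start = 0L, length = as.integer(fragment_length),
                        is_contaminant = FALSE)
      if (mode == "bulk") {
        cap <- max(droplet_count * droplet_capacity, n)
        amplify_bulk(tpl, gain_sigma, cap, gain_scale = gain_scale)$yield_au
      } else {
        part <- structure(list(droplet_count = droplet_count,
                               assignment = sample.int(droplet_count, n, TRUE),
                               template_id = tpl$template_id,
                               occupancy_lambda = n / droplet_count),
                          class = "droplet_partition")
        amplify_emulsion(tpl, part, gain_sigma, droplet_capacity,
                         gain_scale = gain_scale)$yield_au
      }
    }, numeric(1))
    data.frame(lambda = lambdas, mode = mode, yield_au = yields)
  })
}
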