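tpl_pool <- function(n, len = 500L) {
  fragment_templates(mock_community("g", 1), c(g = 50000L), n, len,
                     fragment_length_sd = 0, seed = 42)
}

test_that("bulk amplification: degenerate gains, capacity cap and conservation", {
  tpl <- tpl_pool(10)
  # gain_sigma = 0 with huge capacity: every copy number identical
  res <- amplify_bulk(tpl, 0, 1e9, seed = 1)
  expect_true(all(res$copies == res$copies[1]))
  expect_equal(res$yield_au, sum(res$copies * tpl$length))

  # single template with raw gain far above capacity K: copies = K exactly
  one <- tpl_pool(1)
  res <- amplify_bulk(one, 0, 50, seed = 1, gain_scale = 1000)
  expect_equal(res$copies, 50)

  # capacity binding: total copies equal the reaction capacity exactly
  tpl <- tpl_pool(500)
  res <- amplify_bulk(tpl, 2, 10000, seed = 2)
  expect_equal(sum(res$copies), 10000)

  expect_error(amplify_bulk(tpl, -1, 1e6), class = "dropmda_argument_error")
  expect_error(amplify_bulk(tpl, 2, 10), class = "dropmda_argument_error")
})

test_that("heavier gain tails drop more templates to zero copies", {
  tpl <- tpl_pool(2000)
  zero_frac <- function(sigma, seed)
    mean(amplify_bulk(tpl, sigma, 2e5, seed = seed)$copies == 0)
  heavy <- vapply(1:10, function(s) zero_frac(2, s), numeric(1))
  light <- vapply(1:10, function(s) zero_frac(0.1, s + 100), numeric(1))
  expect_true(all(heavy > max(light)))
})

test_that("emulsion amplification saturates per droplet and conserves budget", {
  tpl <- tpl_pool(50)
  # every droplet singly occupied, all gains above droplet capacity
  part <- structure(list(droplet_count = 50L, assignment = 1:50,
                         template_id = tpl$template_id,
                         occupancy_lambda = 1),
                    class = "droplet_partition")
  res <- amplify_emulsion(tpl, part, 0, 400, seed = 1, gain_scale = 1000)
  expect_true(all(res$copies == 400))
  expect_equal(res$yield_au, sum(400 * tpl$length))

  # empty pool: zero yield
  empty <- tpl_pool(1)[0, ]
  part0 <- partition_into_droplets(empty, 10, 0.01, seed = 1)
  expect_equal(amplify_emulsion(empty, part0, 2, 400, seed = 1)$yield_au, 0)

  # crowded droplets never exceed the per-droplet budget
  tpl <- tpl_pool(3000)
  part <- partition_into_droplets(tpl, 10, 0.01, seed = 3)  # lambda = 3
  res <- amplify_emulsion(tpl, part, 2, 400, seed = 3)
  per_droplet <- tapply(res$copies, part$assignment, sum)
  expect_true(all(per_droplet <= 400))

  bad <- part; bad$template_id <- bad$template_id + 1L
  expect_error(amplify_emulsion(tpl, bad, 2, 400),
               class = "dropmda_consistency_error")
})

test_that("unamplified mode keeps every template at one copy", {
  tpl <- tpl_pool(20)
  res <- amplify_none(tpl)
  expect_true(all(res$copies == 1))
  expect_equal(res$yield_au, sum(tpl$length))
  expect_equal(res$mode, "unamplified")
})

test_that("partitioning reduces copy-number dispersion at low occupancy", {
  n_rep <- 50
  wins <- vapply(seq_len(n_rep), function(s) {
    tpl <- tpl_pool(500)
    part <- partition_into_droplets(tpl, 10, 0.025, seed = s)  # lambda 0.2
    em <- amplify_emulsion(tpl, part, 2, 400, seed = s)
    bk <- amplify_bulk(tpl, 2, 2500 * 400, seed = s + 1000)
    cv <- function(x) stats::sd(x) / mean(x)
    cv(em$copies) < cv(bk$copies)
  }, logical(1))
  expect_gte(sum(wins), 45)
})

test_that("yield curves: monotone emulsion yield tracking droplet occupancy", {
  lam <- c(0.05, 0.2, 1, 5)
  # gain_scale far above capacity: every occupied droplet saturates, so the
  # closed form droplet_count * (1 - exp(-lambda)) * capacity applies
  ye <- simulate_yield_curve(lam, "emulsion", droplet_count = 2e4,
                             droplet_capacity = 400, gain_scale = 1e5,
                             fragment_length = 500, seed = 8)
  expect_true(all(diff(ye$yield_au) > 0))
  closed <- 2e4 * (1 - exp(-lam)) * 400 * 500
  # occupied-droplet count is binomial(droplet_count, 1 - exp(-lambda))
  sd_occ <- sqrt(2e4 * (1 - exp(-lam)) * exp(-lam)) * 400 * 500
  expect_true(all(abs(ye$yield_au - closed) < 3 * sd_occ + 0.01 * closed))

  expect_error(simulate_yield_curve(c(0.1, -1), "bulk"),
               class = "dropmda_argument_error")
})
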