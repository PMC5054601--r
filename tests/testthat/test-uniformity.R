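test_that("Lorenz curve reproduces the worked examples", {
  # constant depth: the diagonal of perfect uniformity
  lc <- lorenz_curve(depth_vector("g", c(2, 2, 2, 2)))
  expect_equal(lc$y, lc$x)

  lc <- lorenz_curve(depth_vector("g", c(1, 1, 2, 4)))
  expect_equal(lc$x, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(lc$y, c(0, 0.125, 0.25, 0.5, 1))

  # covered_only basis drops zero-depth positions
  lc <- lorenz_curve(depth_vector("g", c(0, 0, 3, 3)))
  expect_equal(lc$x, c(0, 0.5, 1))
  expect_equal(lc$y, lc$x)

  lcw <- lorenz_curve(depth_vector("g", c(0, 0, 3, 3)), basis = "whole_genome")
  expect_equal(lcw$y, c(0, 0, 0, 0.5, 1))

  expect_error(lorenz_curve(depth_vector("g", c(0, 0))),
               class = "dropmda_undefined_statistic")
})

test_that("Lorenz curves are nondecreasing, convex and end at (1,1)", {
  set.seed(4)
  for (i in 1:25) {
    d <- depth_vector("g", rpois(sample(5:80, 1), sample(1:10, 1)))
    if (sum(d$depth) == 0) next
    lc <- lorenz_curve(d)
    expect_true(all(diff(lc$y) >= -1e-15))
    expect_true(all(diff(diff(lc$y)) >= -1e-12))  # sorted ascending => convex
    expect_equal(c(lc$x[length(lc$x)], lc$y[length(lc$y)]), c(1, 1))
  }
})

test_that("gini matches hand-derived values and scale identities", {
  d <- depth_vector("g", c(1, 1, 2, 4))
  expect_equal(gini(d), 0.3125)
  expect_equal(gini(d, scale = "area"), 0.15625)
  expect_equal(gini(lorenz_curve(d)), 0.3125)

  # diagonal: zero on both scales
  const <- depth_vector("g", rep(7, 10))
  expect_equal(gini(const), 0)
  expect_equal(gini(const, scale = "area"), 0)

  # all mass on one of N positions (whole-genome basis): gini = 1 - 1/N
  for (N in c(10, 100, 1000)) {
    one <- depth_vector("g", c(rep(0, N - 1), 50))
    expect_equal(gini(one, basis = "whole_genome"), 1 - 1 / N)
  }

  bad <- structure(list(x = c(0, 0.5, 1), y = c(0, 0.8, 1), basis = "covered_only"),
                   class = "lorenz_curve")
  bad$y <- c(0, 0.8, 0.5)
  expect_error(gini(bad), class = "dropmda_invariant_error")
})

test_that("midpoint-rule gini equals the shoelace polygon area exactly", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    d <- rpois(n, sample(1:8, 1))
    if (sum(d) == 0) d[1] <- 1
    dv <- depth_vector("g", d)
    expect_equal(gini(dv), gini_shoelace(d), tolerance = 1e-12)
    if (any(d > 0))
      expect_equal(gini(dv, basis = "whole_genome"),
                   gini_shoelace(d, basis = "whole_genome"), tolerance = 1e-12)
    expect_equal(gini(dv), 2 * gini(dv, scale = "area"), tolerance = 1e-15)
    expect_gte(gini(dv), -1e-12)
    expect_lte(gini(dv), 1)
  }
})

test_that("CV matches the direct formula and its invariances", {
  d <- depth_vector("g", c(1, 1, 2, 4))
  expect_equal(coefficient_of_variation(d), 100 * sqrt(1.5) / 2)
  expect_equal(round(coefficient_of_variation(d), 3), 61.237)
  expect_equal(coefficient_of_variation(depth_vector("g", rep(3, 9))), 0)

  set.seed(6)
  x <- rpois(100, 4) + 1
  expect_equal(coefficient_of_variation(depth_vector("g", x)),
               coefficient_of_variation(depth_vector("g", 7 * x)))
  expect_error(coefficient_of_variation(depth_vector("g", rep(0, 5))),
               class = "dropmda_undefined_statistic")
})

test_that("all statistics are invariant under position permutation", {
  set.seed(7)
  d <- rpois(500, 3)
  dv <- depth_vector("g", d)
  pv <- depth_vector("g", sample(d))
  expect_equal(gini(dv), gini(pv))
  expect_equal(coefficient_of_variation(dv), coefficient_of_variation(pv))
  expect_equal(breadth(dv), breadth(pv))
})

test_that("uniformity report bundles breadth, CV and gini", {
  rep_ <- uniformity_report(depth_vector("g", rep(4, 12)))
  expect_equal(rep_$breadth_percent, 100)
  expect_equal(rep_$cv_percent, 0)
  expect_equal(rep_$gini, 0)
  expect_error(uniformity_report(depth_vector("g", rep(0, 12))),
               class = "dropmda_undefined_statistic")
})
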