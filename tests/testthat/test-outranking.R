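ref_system <- praziquantel_data("boundaries")
ref_thresholds <- praziquantel_data("thresholds")

test_that("partial concordance follows the q/p interpolation on both branches", {
  # full support at or above reference - q; zero at deficit >= p; linear between
  expect_equal(partial_concordance(0.714, 0.71, q = 0, p = 0.05), 1.0)
  expect_equal(partial_concordance(0.71, 0.714, q = 0, p = 0.05), 0.92)
  expect_equal(partial_concordance(0.30, 0.44, q = 0, p = 0.05), 0.0)
  # p == q degenerates to a step at reference - q
  expect_equal(partial_concordance(c(0.99, 1.0, 1.01), 1.0, q = 0, p = 0),
               c(0, 1, 1))
  expect_error(partial_concordance(1, 1, q = 0.1, p = 0.05), "0 <= q <= p")
})

test_that("partial discordance follows the p/v interpolation and the veto edge", {
  expect_equal(partial_discordance(0.324, 0.44, p = 0.05, v = 0.10), 1.0)
  expect_equal(partial_discordance(0.38, 0.44, p = 0.05, v = 0.10), 0.2)
  expect_equal(partial_discordance(0.50, 0.44, p = 0.05, v = 0.10), 0.0)
  # a deficit of exactly v vetoes
  expect_equal(partial_discordance(0.9, 1.0, p = 0.05, v = 0.10), 1.0)
  expect_error(partial_discordance(1, 1, p = 0.05, v = 0.05), "veto")
})

test_that("monotonicity: concordance nondecreasing, discordance nonincreasing in value", {
  set.seed(42)
  for (i in 1:200) {
    ref <- runif(1, 0, 2)
    q <- runif(1, 0, 0.05); p <- q + runif(1, 0, 0.1); v <- p + runif(1, 0.01, 0.2)
    vals <- sort(runif(25, 0, 2))
    cc <- partial_concordance(vals, ref, q, p)
    dd <- partial_discordance(vals, ref, p, v)
    expect_true(all(diff(cc) >= 0))
    expect_true(all(diff(dd) <= 0))
    expect_true(all(cc >= 0 & cc <= 1 & dd >= 0 & dd <= 1))
  }
})

test_that("global concordance is the weighted mean of partials", {
  expect_equal(global_concordance(c(1, 1, 1, 1), rep(0.25, 4)), 1.0)
  expect_equal(global_concordance(c(1, 1, 0.58, 0.30), rep(0.25, 4)), 0.72)
  expect_equal(global_concordance(c(0, 0, 0, 0), rep(0.25, 4)), 0.0)
  expect_error(global_concordance(c(1, 0), rep(0.25, 4)), "length")
})

test_that("credibility discounts strong discordances and honours the veto", {
  expect_equal(credibility(0.8, c(0, 0, 0, 0)), 0.8)
  expect_equal(credibility(0.75, c(1, 0, 0, 0)), 0.0)
  # only discordances exceeding the global concordance contribute a factor
  expect_equal(credibility(0.5, c(0.32, 0.84, 0, 0)), 0.5 * (1 - 0.84) / 0.5)
  expect_equal(credibility(1, c(0.3, 0.9, 0, 0)), 1)
})

test_that("credibility pair reproduces the borderline authentic sample's indices", {
  sig <- credibility_pair(c(0.714, 0.45, 0.474, 0.412),
                          ref_system$lower_boundary, ref_thresholds)
  expect_equal(sig[["sigma_ab"]], 1.0)
  expect_equal(sig[["sigma_ba"]], mean(c(0.92, 0.80, 0.72, 0.76)))
  # identity: any profile vs itself with q = 0 outranks both ways
  x <- c(0.5, 1.2, 0.3, 1.9)
  sig <- credibility_pair(x, x, ref_thresholds)
  expect_equal(unname(sig), c(1, 1))
})

test_that("the four-way relation is a pure function of the two cuts", {
  expect_identical(outranking_relation(1.0, 0.80, 0.85), "sample_preferred")
  expect_identical(outranking_relation(1.0, 0.80, 0.75), "indifferent")
  expect_identical(outranking_relation(0.3, 0.2, 0.85), "incomparable")
  expect_identical(outranking_relation(0.2, 0.9, 0.85), "boundary_preferred")
})

test_that("pessimistic and optimistic assignments place reference samples correctly", {
  cases <- list(
    list(a = c(0.907, 0.584, 0.56, 0.478), pess = "CAT-A", opti = "CAT-A"),
    list(a = c(2, 2, 2, 2),                pess = "CAT-C", opti = "CAT-C"),
    list(a = c(0.357, 0.194, 0.203, 0.205), pess = "CAT-B", opti = "CAT-B"))
  for (cs in cases) {
    s <- fp4("x", cs$a)
    expect_identical(assign_pessimistic(s, ref_system, ref_thresholds), cs$pess)
    expect_identical(assign_optimistic(s, ref_system, ref_thresholds), cs$opti)
  }
  wrong_grid <- fingerprint("y", c(240, 250), c(1, 1))
  expect_error(assign_pessimistic(wrong_grid, ref_system, ref_thresholds),
               "grid")
})

test_that("engine agrees with the loop-based scalar oracle on random instances", {
  set.seed(1234)
  for (i in 1:1000) {
    inst <- random_instance()
    ts <- suppressWarnings(
      threshold_set(q = inst$q, p = inst$p, v = inst$v, lambda = 0.85,
                    weights = inst$weights))
    got <- credibility_pair(inst$values, inst$boundary, ts)
    want <- oracle_pair(inst$values, inst$boundary,
                        inst$q, inst$p, inst$v, inst$weights)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("sandwich property: samples more than p inside both boundaries are CAT-A at any lambda", {
  set.seed(99)
  for (i in 1:40) {
    sys <- random_system(min_gap = 0.25)
    p <- 0.05
    a <- runif(4, sys$lower_boundary + p + 1e-6, sys$upper_boundary - p - 1e-6)
    s <- fp4("inside", a)
    for (lam in c(0.51, 0.75, 0.85, 1)) {
      ts <- threshold_set(p = p, v = 0.10, lambda = lam)
      expect_identical(assign_pessimistic(s, sys, ts), "CAT-A")
      expect_identical(assign_optimistic(s, sys, ts), "CAT-A")
      expect_identical(classify(s, sys, ts)$verdict, "Authentic")
    }
  }
})

test_that("veto property: a single deviation of v or more outside a boundary forbids Authentic", {
  set.seed(7)
  v <- 0.10
  ts <- threshold_set(p = 0.05, v = v, lambda = 0.85)
  for (i in 1:100) {
    sys <- random_system()
    a <- runif(4, sys$lower_boundary, sys$upper_boundary)
    j <- sample(4, 1L)
    if (runif(1) < 0.5) {
      a[j] <- max(sys$lower_boundary[j] - v - runif(1, 0, 0.3), 0)
      if (sys$lower_boundary[j] - a[j] < v) next  # clipped at the 0 end
    } else {
      a[j] <- min(sys$upper_boundary[j] + v + runif(1, 0, 0.3), 2)
      if (a[j] - sys$upper_boundary[j] < v) next  # clipped at the 2 end
    }
    expect_identical(classify(fp4("dev", a), sys, ts)$verdict, "LQC")
  }
})
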