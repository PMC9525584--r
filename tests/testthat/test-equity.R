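# Lorenz curves, Suits Index, county decomposition, dispersity.

test_that("DAC classification uses the score >= 75 boundary", {
  expect_true(classify_dac(75))
  expect_false(classify_dac(74.99))
  expect_true(classify_dac(100))
  expect_false(classify_dac(0))
  expect_equal(classify_dac(c(10, 75, 80)), c(FALSE, TRUE, TRUE))
  expect_error(classify_dac(101), "\\[0, 100\\]")
})

test_that("lorenz_curve construction matches hand-built cases", {
  # benefits proportional to population: every point on y = x
  tr <- make_tracts(4, population = c(10, 20, 30, 40))
  lc <- lorenz_curve(tr, benefits = c(1, 2, 3, 4))
  expect_equal(lc$x, lc$y)
  expect_equal(lc$x[1], 0)
  expect_equal(lc$x[length(lc$x)], 1)
  # two equal-population tracts, scores {10, 90}, benefits {0, B}
  tr2 <- make_tracts(2, population = c(50, 50), score = c(10, 90))
  lc2 <- lorenz_curve(tr2, benefits = c(0, 7))
  expect_equal(lc2$x, c(0, 0.5, 1))
  expect_equal(lc2$y, c(0, 0, 1))
  # permutation invariance (deterministic score/tract_id sort)
  perm <- c(3, 1, 4, 2)
  lc3 <- lorenz_curve(tr[perm, ], benefits = setNames(c(1, 2, 3, 4), tr$tract_id)[perm])
  expect_equal(lc3$x, lc$x)
  expect_equal(lc3$y, lc$y)
  expect_identical(lc3$tract_id, lc$tract_id)
  expect_error(lorenz_curve(tr, benefits = rep(0, 4)), "zero")
})

test_that("suits_index reproduces the analytic toy curves", {
  tr <- make_tracts(4, population = c(10, 20, 30, 40))
  expect_equal(suits_index(tr, benefits = c(1, 2, 3, 4))$suits_index, 0)
  tr2 <- make_tracts(2, population = c(50, 50), score = c(10, 90))
  # (0,0),(0.5,0),(1,1): L = 0.25 -> S = +0.5
  expect_equal(suits_index(tr2, benefits = c(0, 1))$suits_index, 0.5)
  # (0,0),(0.5,1),(1,1): L = 0.75 -> S = -0.5
  expect_equal(suits_index(tr2, benefits = c(1, 0))$suits_index, -0.5)
})

test_that("S stays in [-1, 1] for nonnegative benefits and attains the edges", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:100, 1)
    tr <- make_tracts(n, population = runif(n, 1, 1e4),
                      score = runif(n, 0, 100))
    s <- suits_index(tr, benefits = runif(n))$suits_index
    expect_gte(s, -1); expect_lte(s, 1)
  }
  # discrete extremes: lone benefiting tract with vanishing population share
  n <- 10000
  tr <- make_tracts(n, population = rep(1, n))
  ben <- c(rep(0, n - 1), 1)            # all benefit in the top-ranked tract
  expect_equal(suits_index(tr, benefits = ben)$suits_index, 1,
               tolerance = 2 / n)
  ben0 <- c(1, rep(0, n - 1))           # all benefit in the bottom-ranked tract
  expect_equal(suits_index(tr, benefits = ben0)$suits_index, -1,
               tolerance = 2 / n)
})

test_that("trapezoid S agrees with a fine Riemann oracle within 1e-6", {
  set.seed(17)
  for (i in 1:10) {
    n <- 100
    tr <- make_tracts(n, population = rlnorm(n, log(5000), 0.5),
                      score = runif(n, 0, 100))
    ben <- rlnorm(n, 0, 1)
    lc <- lorenz_curve(tr, ben)
    s <- suits_index(lc)$suits_index
    expect_equal(s, riemann_suits(lc), tolerance = 1e-6)
  }
})

test_that("county decomposition renormalizes within county", {
  # single county: county S equals statewide S
  tr <- make_tracts(6, population = runif(6, 10, 100), score = runif(6, 0, 100))
  set.seed(3); ben <- runif(6)
  cty <- suits_by_county(tr, ben)
  expect_equal(nrow(cty), 1)
  expect_equal(cty$suits_index, suits_index(tr, benefits = ben)$suits_index)
  # two counties; within-county proportional benefits give S = 0 even though
  # the county totals differ from their population shares
  tr2 <- make_tracts(4, population = c(10, 30, 20, 20),
                     score = c(20, 80, 30, 70),
                     county = c("A", "A", "B", "B"))
  ben2 <- c(1, 3, 200, 200)   # proportional within A and within B
  cty2 <- suits_by_county(tr2, ben2)
  expect_equal(cty2$suits_index, c(0, 0))
  # single-tract county: S = 0 by construction
  tr3 <- make_tracts(3, county = c("A", "A", "B"))
  cty3 <- suits_by_county(tr3, c(1, 2, 3))
  expect_equal(cty3$suits_index[cty3$county_id == "B"], 0)
  # zero-benefit county flagged with NA index
  cty4 <- suits_by_county(tr3, c(1, 2, 0))
  expect_true(is.na(cty4$suits_index[cty4$county_id == "B"]))
  expect_true(cty4$zero_benefit[cty4$county_id == "B"])
})

test_that("scenario equity deltas are antisymmetric elementwise differences", {
  a <- data.frame(county_id = c("A", "B"), avoided_deaths = c(10, 5),
                  suits_index = c(0.2, -0.1))
  b <- data.frame(county_id = c("B", "A"), avoided_deaths = c(4, 9),
                  suits_index = c(0.3, 0.15))
  d <- scenario_delta_equity(a, b)
  expect_equal(d$delta_suits[d$county_id == "B"], -0.4)
  expect_equal(d$delta_avoided_deaths, c(1, 1))
  z <- scenario_delta_equity(a, a)
  expect_true(all(z$delta_avoided_deaths == 0 & z$delta_suits == 0))
  neg <- scenario_delta_equity(b, a)
  expect_equal(neg$delta_suits, -d$delta_suits)
  expect_error(scenario_delta_equity(a, b[1, ]), "differ")
})

test_that("dispersity is the min-max-normalized population sd", {
  expect_equal(dispersity(c(0, 1, 2))$sigma, sqrt(1 / 6))
  expect_equal(dispersity(c(0, 1, 2))$sigma, 0.40825, tolerance = 1e-5)
  expect_equal(dispersity(rep(3.3, 5))$sigma, 0)
  set.seed(5); b <- rlnorm(50)
  expect_equal(dispersity(10 * b)$sigma, dispersity(b)$sigma)
  expect_error(dispersity(1), ">= 2")
})

test_that("statewide S increases monotonically with generator rho", {
  rhos <- c(-0.5, 0, 0.5, 0.9)
  means <- sapply(rhos, function(rho) {
    mean(sapply(1:20, function(rep) {
      r <- generate_region(region_spec(n_tracts = 500, n_counties = 8,
                                       benefit_vulnerability_rho = rho,
                                       seed = 9000 + 37 * rep))
      dc <- aggregate_to_tracts(r$scenario_deltas[[1]], r$weights)
      imp <- impact_assessment(r$tracts, dc, pooling = "fixed")
      suits_index(r$tracts,
                  benefits = setNames(imp$avoided_deaths, imp$tract_id))$suits_index
    }))
  })
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 0)   # regressive coupling gives a negative index
  expect_gt(means[4], 0)
})

test_that("equity outputs are invariant under tract reordering", {
  r <- generate_region(small_spec(seed = 23))
  dc <- aggregate_to_tracts(r$scenario_deltas[[1]], r$weights)
  imp <- impact_assessment(r$tracts, dc, pooling = "fixed")
  ben <- setNames(imp$avoided_deaths, imp$tract_id)
  perm <- sample(nrow(r$tracts))
  s1 <- suits_index(r$tracts, benefits = ben)
  s2 <- suits_index(r$tracts[perm, ], benefits = ben)
  expect_equal(s1$suits_index, s2$suits_index)
  expect_equal(suits_by_county(r$tracts, ben),
               suits_by_county(r$tracts[perm, ], ben))
  expect_equal(dispersity(ben)$sigma, dispersity(ben[perm])$sigma)
})
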