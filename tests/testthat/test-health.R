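# Log-linear health impact function, effect pooling, tract assessment.

test_that("avoided_cases matches the closed form and its limits", {
  # direct evaluation: 0.008 * 1e4 * (1 - exp(-0.005827))
  expect_equal(avoided_cases(0.008, 1e4, 0.005827, 1.0), 0.4648045,
               tolerance = 1e-6)
  expect_identical(avoided_cases(0.008, 1e4, 0.005827, 0), 0)
  # saturation: approaches incidence * population from below
  sat <- avoided_cases(0.008, 1e4, 20, 1.0)
  expect_lt(sat, 80)
  expect_equal(sat, 80, tolerance = 1e-8)
  # negative delta gives negative avoided cases
  expect_lt(avoided_cases(0.008, 1e4, 0.005827, -0.5), 0)
  expect_error(avoided_cases(0.008, 1e4, NaN, 1), "finite")
})

test_that("small-signal limit agrees with the linearized form within 0.1%", {
  set.seed(2)
  for (i in 1:50) {
    beta <- runif(1, 1e-4, 1e-2)
    dc <- runif(1, 1e-3, 1e-1)
    if (abs(beta * dc) >= 1e-3) next
    full <- avoided_cases(0.008, 1e4, beta, dc)
    lin <- 0.008 * 1e4 * beta * dc
    expect_equal(full, lin, tolerance = 1e-3)
  }
})

test_that("avoided_cases is monotone in beta, delta_c, pop and incidence", {
  base <- avoided_cases(0.008, 1e4, 0.006, 1)
  expect_gt(avoided_cases(0.008, 1e4, 0.007, 1), base)
  expect_gt(avoided_cases(0.008, 1e4, 0.006, 1.5), base)
  expect_gt(avoided_cases(0.008, 2e4, 0.006, 1), base)
  expect_gt(avoided_cases(0.009, 1e4, 0.006, 1), base)
})

test_that("fixed-effects pooling matches the hand inverse-variance example", {
  eff <- list(crf("a", beta = 0.006, se = 0.002),
              crf("b", beta = 0.010, se = 0.004))
  p <- pool_fixed(eff)
  expect_equal(p$beta, 0.0068)
  expect_equal(p$se, sqrt(1 / 312500))       # 0.0017889
  expect_equal(p$se, 0.0017889, tolerance = 1e-4)
  # single effect returned unchanged
  single <- pool_fixed(list(crf("a", beta = 0.006, se = 0.002)))
  expect_equal(single$beta, 0.006)
  expect_equal(single$se, 0.002)
  # two identical effects: variance halves
  twin <- pool_fixed(list(crf("a", beta = 0.006, se = 0.002),
                          crf("b", beta = 0.006, se = 0.002)))
  expect_equal(twin$beta, 0.006)
  expect_equal(twin$se, 0.002 / sqrt(2))
  expect_error(pool_fixed(list(crf("a", beta = 0.006, se = 0))), "degenerate")
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  # w = 250000 each; beta_f = 0.013; Q = 24.5; C = 250000
  # tau2 = (24.5 - 1)/250000 = 9.4e-5; se = sqrt((0.002^2 + tau2)/2) = 0.007
  eff <- list(crf("a", beta = 0.006, se = 0.002),
              crf("b", beta = 0.020, se = 0.002))
  p <- pool_random(eff)
  expect_equal(p$heterogeneity_Q, 24.5)
  expect_equal(p$tau2, 9.4e-5)
  expect_equal(p$beta, 0.013)
  expect_equal(p$se, 0.007)
  expect_gt(p$se, pool_fixed(eff)$se)
  # homogeneous inputs reduce to fixed effects
  hom <- list(crf("a", beta = 0.006, se = 0.002),
              crf("b", beta = 0.0062, se = 0.002))
  pr <- pool_random(hom); pf <- pool_fixed(hom)
  expect_equal(pr$tau2, 0)
  expect_equal(pr$beta, pf$beta, tolerance = 1e-12)
  expect_equal(pr$se, pf$se, tolerance = 1e-12)
  # identical effects: tau2 = 0
  expect_equal(pool_random(list(crf("a", beta = 0.006, se = 0.002),
                                crf("b", beta = 0.006, se = 0.002)))$tau2, 0)
  expect_error(pool_random(list(crf("a", beta = 0.006, se = 0.002))), ">= 2")
})

test_that("auto pooling follows the Cochran-Q chi-square rule", {
  het <- list(crf("a", beta = 0.006, se = 0.002),
              crf("b", beta = 0.020, se = 0.002))   # Q = 24.5 > 3.84
  expect_equal(pool_effects(het, "auto")$method, "random")
  hom <- list(crf("a", beta = 0.006, se = 0.002),
              crf("b", beta = 0.007, se = 0.002))   # Q = 0.125 < 3.84
  expect_equal(pool_effects(hom, "auto")$method, "fixed")
  expect_error(pool_effects(het, "nonsense"))
})

test_that("pool_random with tau2 forced to zero equals pool_fixed", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    eff <- lapply(seq_len(k), function(j)
      crf(letters[j], beta = rnorm(1, 0.006, 0.003), se = runif(1, 1e-3, 1e-2)))
    pf <- pool_fixed(eff)
    pr <- pool_random(eff)
    if (pr$tau2 == 0) {
      expect_equal(pr$beta, pf$beta, tolerance = 1e-12)
      expect_equal(pr$se, pf$se, tolerance = 1e-12)
    } else {
      expect_gte(pr$se, pf$se)
    }
  }
})

test_that("impact_assessment applies the pooled coefficient per tract", {
  tr <- make_tracts(1, population = 1e4, incidence = 0.008)
  exp1 <- data.frame(tract_id = "T001", delta_c = 1.0)
  crfs <- list(crf("a", beta = 0.006, se = 0.002),
               crf("b", beta = 0.010, se = 0.004))
  hi <- impact_assessment(tr, exp1, crfs = crfs, pooling = "fixed")
  expect_equal(hi$avoided_deaths, 0.008 * 1e4 * (1 - exp(-0.0068)))
  expect_equal(hi$avoided_deaths, 0.54216, tolerance = 1e-4)
  expect_gt(hi$avoided_deaths_se, 0)
  # all-zero exposure -> all-zero table
  tr5 <- make_tracts(5)
  z <- impact_assessment(tr5, setNames(rep(0, 5), tr5$tract_id), crfs = crfs)
  expect_true(all(z$avoided_deaths == 0))
  # partition conservation and row order
  r <- generate_region(small_spec(seed = 13))
  dc <- aggregate_to_tracts(r$scenario_deltas[[1]], r$weights)
  hi2 <- impact_assessment(r$tracts, dc, crfs = crfs)
  expect_identical(hi2$tract_id, sort(r$tracts$tract_id))
  by_county <- tapply(hi2$avoided_deaths, hi2$county_id, sum)
  expect_equal(sum(by_county), sum(hi2$avoided_deaths))
  # invariant: |avoided deaths| <= population * incidence; sign matches delta
  tr_s <- r$tracts[order(r$tracts$tract_id), ]
  expect_true(all(abs(hi2$avoided_deaths) <=
                    tr_s$population * tr_s$incidence + 1e-12))
  expect_true(all(sign(hi2$avoided_deaths) == sign(hi2$delta_c) |
                    hi2$delta_c == 0))
  expect_error(impact_assessment(tr5, c(T001 = 1)), "differ")
})

test_that("a known beta is recovered from aggregate avoided deaths", {
  r <- generate_region(small_spec(seed = 21, n_tracts = 120))
  dc <- aggregate_to_tracts(r$scenario_deltas[[1]], r$weights)
  beta_star <- log(1.06) / 10
  tr_s <- r$tracts[order(r$tracts$tract_id), ]
  total <- sum(avoided_cases(tr_s$incidence, tr_s$population, beta_star,
                             dc[tr_s$tract_id]))
  beta_hat <- infer_beta(total, r$tracts, dc)
  expect_equal(beta_hat, beta_star, tolerance = 1e-6)
})
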