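# Shared fixtures and independent oracles, built in code at test time.

# Minimal tract table constructor.
make_tracts <- function(n, population = rep(1000, n),
                        incidence = rep(0.008, n),
                        score = seq(0, 100, length.out = max(n, 2))[seq_len(n)],
                        county = rep("C01", n)) {
  data.frame(tract_id = sprintf("T%03d", seq_len(n)), county_id = county,
             population = population, incidence = incidence,
             vulnerability_score = score, stringsAsFactors = FALSE)
}

# Independent Suits oracle: fine-grained midpoint Riemann sum over the
# piecewise-linear Lorenz curve (never calls the trapezoid path).
riemann_suits <- function(curve, n_steps = 2e5) {
  xm <- (seq_len(n_steps) - 0.5) / n_steps
  ym <- approx(curve$x, curve$y, xout = xm, ties = "ordered")$y
  L <- sum(ym) / n_steps
  (0.5 - L) / 0.5
}

# Achieved Spearman correlation between vulnerability score and per-capita
# tract concentration reduction for one scenario of a region.
achieved_rho <- function(region, scenario = 1L) {
  dc <- aggregate_to_tracts(region$scenario_deltas[[scenario]], region$weights)
  sc <- region$tracts$vulnerability_score[order(region$tracts$tract_id)]
  cor(sc, dc[sort(region$tracts$tract_id)], method = "spearman")
}

# Small fast region spec for pipeline tests.
small_spec <- function(seed = 7, n_tracts = 60, rho = 0.5, ...) {
  region_spec(n_tracts = n_tracts, n_counties = 4, grid_rows = 12,
              grid_cols = 12, smoothing_length = 2,
              benefit_vulnerability_rho = rho, seed = seed, ...)
}
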