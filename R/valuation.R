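# Valuation: VSL monetization, per-capita cost allocation, cost per life
# saved, and net-benefit summaries.

#' Monetize avoided deaths with a value of a statistical life
#'
#' @param avoided_deaths deaths per year (vectorized).
#' @param vsl value of a statistical life, USD per death (2018$);
#'   default $9.7 million.
#' @return USD per year.
#' @examples
#' monetize(6100)  # ~5.917e10, i.e. ~$59 billion
#' @export
monetize <- function(avoided_deaths, vsl = 9.7e6) {
  check_positive(vsl, "vsl")
  avoided_deaths * vsl
}

#' Allocate an economy-wide mitigation cost across tracts per capita
#'
#' Assumes every resident pays an equal share: the per-capita cost is
#' `total_cost / sum(population)` and a tract's allocated cost is the sum of
#' its residents' shares.
#'
#' @param total_cost economy-wide incremental annual cost, USD/yr.
#' @param tracts tract table.
#' @return named numeric vector of per-tract allocated costs (USD/yr), in
#'   `tracts` row order; sums to `total_cost` up to rounding.
#' @export
allocate_costs <- function(total_cost, tracts) {
  check_scalar_number(total_cost, "total_cost")
  check_tracts(tracts)
  total_pop <- sum(tracts$population)
  if (total_pop <= 0) stop_cb("total population must be > 0")
  out <- total_cost / total_pop * tracts$population
  names(out) <- tracts$tract_id
  out
}

#' Implicit mitigation cost per life saved in a tract
#'
#' The tract's allocated cost divided by its avoided deaths.  Tracts with
#' zero or negative avoided deaths receive `Inf` (no finite cost per life;
#' they can never show a net benefit) rather than being dropped, so that
#' population shares remain well-defined.
#'
#' @param tract_cost allocated cost, USD/yr (>= 0, vectorized).
#' @param avoided_deaths deaths per year (vectorized).
#' @return USD per death, `Inf` where `avoided_deaths <= 0`.
#' @export
cost_per_life <- function(tract_cost, avoided_deaths) {
  if (any(tract_cost < 0)) stop_cb("'tract_cost' must be >= 0")
  ifelse(avoided_deaths > 0, tract_cost / avoided_deaths, Inf)
}

#' Tract-level valuation table
#'
#' Combines a health-impact table with a scenario's economy-wide cost:
#' monetized benefit, per-capita allocated cost, implicit cost per life
#' saved, and the net-benefit flag (`cost_per_life < vsl`, strict).
#'
#' @param impact `health_impact` table from [impact_assessment()].
#' @param tracts tract table.
#' @param total_cost scenario economy-wide incremental cost, USD/yr.
#' @param vsl value of a statistical life, USD (2018$).
#' @return data.frame with columns `tract_id`, `county_id`, `population`,
#'   `avoided_deaths`, `benefit_usd`, `allocated_cost_usd`, `cost_per_life`,
#'   `net_benefit`, ordered by ascending `tract_id`.
#' @export
tract_valuation <- function(impact, tracts, total_cost, vsl = 9.7e6) {
  check_tracts(tracts)
  check_positive(vsl, "vsl")
  if (!all(c("tract_id", "avoided_deaths") %in% names(impact)))
    stop_cb("'impact' must have columns tract_id and avoided_deaths")
  costs <- allocate_costs(total_cost, tracts)
  ord <- order(tracts$tract_id)
  tr <- tracts[ord, , drop = FALSE]
  deaths <- impact$avoided_deaths[match(tr$tract_id, impact$tract_id)]
  if (any(is.na(deaths)))
    stop_cb("impact table missing tract(s): %s",
            paste(tr$tract_id[is.na(deaths)], collapse = ", "))
  cpl <- cost_per_life(costs[tr$tract_id], deaths)
  out <- data.frame(tract_id = tr$tract_id, county_id = tr$county_id,
                    population = tr$population, avoided_deaths = deaths,
                    benefit_usd = monetize(deaths, vsl),
                    allocated_cost_usd = as.numeric(costs[tr$tract_id]),
                    cost_per_life = as.numeric(cpl),
                    net_benefit = as.numeric(cpl) < vsl,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scenario net-benefit summary
#'
#' The cost/benefit shares the assessment reports per scenario: the share of
#' population, of census tracts, and of disadvantaged-community (DAC) tracts
#' whose implicit cost per life saved is below the VSL, plus statewide
#' monetized totals.  The population share weights tracts by population (it
#' counts people living in qualifying tracts).
#'
#' @param valuation table from [tract_valuation()].
#' @param tracts tract table (for DAC classification).
#' @param dac_threshold vulnerability score at or above which a tract is a
#'   disadvantaged community (default 75, the top quartile).
#' @return list with `pop_share_net_benefit`, `tract_share_net_benefit`,
#'   `dac_share_net_benefit` (percent, 0-100; DAC share is `NA` if the
#'   region has no DAC tracts), `total_benefit_usd`, `total_cost_usd`,
#'   `net_benefit_usd`.
#' @export
net_benefit_summary <- function(valuation, tracts, dac_threshold = 75) {
  check_tracts(tracts)
  v <- valuation[match(sort(tracts$tract_id), valuation$tract_id), , drop = FALSE]
  dac <- classify_dac(tracts$vulnerability_score[order(tracts$tract_id)],
                      threshold = dac_threshold)
  nb <- v$net_benefit
  pop <- v$population
  list(
    pop_share_net_benefit = 100 * sum(pop[nb]) / sum(pop),
    tract_share_net_benefit = 100 * mean(nb),
    dac_share_net_benefit = if (any(dac)) 100 * mean(nb[dac]) else NA_real_,
    total_benefit_usd = sum(v$benefit_usd),
    total_cost_usd = sum(v$allocated_cost_usd),
    net_benefit_usd = sum(v$benefit_usd) - sum(v$allocated_cost_usd)
  )
}
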