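# Health impact: log-linear concentration-response functions, effect pooling,
# and tract-level avoided premature mortality.

#' Define a concentration-response function
#'
#' A log-linear concentration-response function for long-term PM2.5
#' all-cause mortality, parameterized by its log-relative-risk coefficient
#' `beta` (per ug/m3) and standard error.  Supply either `beta` directly or
#' `rr_per_10ug`, the relative risk per 10 ug/m3 as cohort studies report
#' it, in which case `beta = log(rr_per_10ug) / 10`.
#'
#' @param name short label, e.g. `"krewski"`.
#' @param beta log-relative-risk per ug/m3 (exclusive with `rr_per_10ug`).
#' @param se standard error of `beta`, per ug/m3; must be >= 0.
#' @param rr_per_10ug relative risk per 10 ug/m3 increment.
#' @param source free-text provenance (citation).
#' @return object of class `crf`.
#' @examples
#' crf("krewski", rr_per_10ug = 1.06, se = 9.63e-4)
#' @export
crf <- function(name, beta = NULL, se, rr_per_10ug = NULL, source = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_cb("'name' must be a non-empty string")
  if (is.null(beta) == is.null(rr_per_10ug))
    stop_cb("supply exactly one of 'beta' or 'rr_per_10ug'")
  if (!is.null(rr_per_10ug)) {
    check_positive(rr_per_10ug, "rr_per_10ug")
    beta <- log(rr_per_10ug) / 10
  }
  check_scalar_number(beta, "beta")
  check_scalar_number(se, "se")
  if (se < 0) stop_cb("'se' must be >= 0 (got %g)", se)
  structure(list(name = name, beta = beta, se = se, source = source),
            class = "crf")
}

#' @export
print.crf <- function(x, ...) {
  cat(sprintf("CRF '%s': beta = %.6g per ug/m3 (se %.3g)  RR per 10 ug/m3 = %.4g\n",
              x$name, x$beta, x$se, exp(10 * x$beta)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Default PM2.5 mortality concentration-response functions
#'
#' The two cohort-based all-cause mortality functions conventionally applied
#' to long-term PM2.5 in BenMAP-style assessments: RR 1.06 per 10 ug/m3
#' (Krewski et al., ACS cohort re-analysis) and RR 1.17 per 10 ug/m3
#' (Jerrett et al., California-specific).  Standard errors are derived from
#' the published 95% confidence intervals (1.04-1.08 and 1.05-1.30); all
#' values are configuration, not constants, and should be overridden when a
#' study prescribes others.
#'
#' @return list of two `crf` objects.
#' @export
default_crfs <- function() {
  list(
    crf("krewski", rr_per_10ug = 1.06,
        se = (log(1.08) - log(1.04)) / (2 * qnorm(0.975)) / 10,
        source = "ACS cohort reanalysis, RR 1.06 (95% CI 1.04-1.08) per 10 ug/m3"),
    crf("jerrett", rr_per_10ug = 1.17,
        se = (log(1.30) - log(1.05)) / (2 * qnorm(0.975)) / 10,
        source = "California cohort, RR 1.17 (95% CI 1.05-1.30) per 10 ug/m3")
  )
}

#' Avoided cases from a concentration reduction
#'
#' The standard log-linear health impact function
#' `delta_Y = Y0 * Pop * (1 - exp(-beta * delta_c))`: avoided deaths per
#' year in a population with baseline incidence `Y0` experiencing an
#' annual-mean concentration reduction `delta_c`.  Negative `delta_c`
#' (worsening) yields negative avoided cases.  Vectorized over tracts.
#'
#' @param incidence baseline all-cause mortality incidence, per person-year.
#' @param population persons.
#' @param beta log-relative-risk per ug/m3.
#' @param delta_c concentration reduction, ug/m3 (positive = improvement).
#' @return avoided deaths per year.
#' @examples
#' avoided_cases(0.008, 1e4, log(1.06) / 10, 1.0)  # ~0.465 deaths/yr
#' @export
avoided_cases <- function(incidence, population, beta, delta_c) {
  if (any(!is.finite(incidence)) || any(!is.finite(population)) ||
      any(!is.finite(beta)) || any(!is.finite(delta_c)))
    stop_cb("avoided_cases: all inputs must be finite")
  if (any(incidence < 0)) stop_cb("'incidence' must be >= 0")
  if (any(population <= 0)) stop_cb("'population' must be > 0")
  incidence * population * (1 - exp(-beta * delta_c))
}

# -- Effect pooling ----------------------------------------------------------

as_effect_table <- function(effects) {
  if (inherits(effects, "crf")) effects <- list(effects)
  if (!length(effects)) stop_cb("need at least one effect to pool")
  if (!all(vapply(effects, inherits, logical(1), "crf")))
    stop_cb("'effects' must be a list of crf objects")
  data.frame(name = vapply(effects, `[[`, character(1), "name"),
             beta = vapply(effects, `[[`, numeric(1), "beta"),
             se = vapply(effects, `[[`, numeric(1), "se"),
             stringsAsFactors = FALSE)
}

new_pooled <- function(beta, se, method, Q, tau2, k) {
  structure(list(beta = beta, se = se, method = method,
                 heterogeneity_Q = Q, tau2 = tau2, k = k),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Pooled effect (%s, k = %d): beta = %.6g (se %.4g), Q = %.4g, tau2 = %.4g\n",
              x$method, x$k, x$beta, x$se, x$heterogeneity_Q, x$tau2))
  invisible(x)
}

#' Fixed-effects (inverse-variance) pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled beta is the weighted mean and pooled
#' se is `(sum w_i)^(-1/2)`.
#'
#' @param effects list of [crf()] objects (>= 1), all with `se > 0`.
#' @return `pooled_effect` with `tau2 = 0` and Cochran's Q.
#' @export
pool_fixed <- function(effects) {
  eff <- as_effect_table(effects)
  if (any(eff$se <= 0))
    stop_cb("fixed-effects pooling requires se > 0 for every effect (degenerate weight)")
  w <- 1 / eff$se^2
  beta <- sum(w * eff$beta) / sum(w)
  Q <- sum(w * (eff$beta - beta)^2)
  new_pooled(beta, sum(w)^-0.5, "fixed", Q, 0, nrow(eff))
}

#' Random-effects (DerSimonian-Laird) pooling
#'
#' Between-study variance `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`
#' with fixed-effects weights `w_i = 1/se_i^2`; pooled mean and se are then
#' inverse-variance with weights `1/(se_i^2 + tau2)`.  When the inputs are
#' homogeneous (`Q <= k-1`), `tau2 = 0` and the result equals [pool_fixed()].
#'
#' @param effects list of [crf()] objects (>= 2), all with `se > 0`.
#' @return `pooled_effect`.
#' @export
pool_random <- function(effects) {
  eff <- as_effect_table(effects)
  if (nrow(eff) < 2L) stop_cb("random-effects pooling requires >= 2 effects")
  if (any(eff$se <= 0)) stop_cb("random-effects pooling requires se > 0 for every effect")
  w <- 1 / eff$se^2
  beta_f <- sum(w * eff$beta) / sum(w)
  Q <- sum(w * (eff$beta - beta_f)^2)
  k <- nrow(eff)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (eff$se^2 + tau2)
  new_pooled(sum(wr * eff$beta) / sum(wr), sum(wr)^-0.5, "random", Q, tau2, k)
}

#' Pool effects with automatic fixed/random selection
#'
#' `method = "auto"` mimics the BenMAP "Random and Fixed Effects" rule:
#' compute Cochran's Q across the effects; if Q exceeds the chi-square 95th
#' percentile on k-1 degrees of freedom, use random effects, otherwise
#' fixed.  A single effect is always returned as-is (fixed).
#'
#' @param effects list of [crf()] objects.
#' @param method `"auto"`, `"fixed"` or `"random"`.
#' @return `pooled_effect`; `$method` records the branch actually used.
#' @export
pool_effects <- function(effects, method = c("auto", "fixed", "random")) {
  method <- match.arg(method)
  eff <- as_effect_table(effects)
  if (method == "fixed" || nrow(eff) == 1L) return(pool_fixed(effects))
  if (method == "random") return(pool_random(effects))
  fx <- pool_fixed(effects)
  k <- nrow(eff)
  if (fx$heterogeneity_Q > qchisq(0.95, df = k - 1)) pool_random(effects) else fx
}

# -- Tract-level assessment --------------------------------------------------

#' Tract-level avoided-mortality assessment
#'
#' Applies the pooled concentration-response coefficient to every tract's
#' concentration reduction with [avoided_cases()].  The per-tract standard
#' error is propagated by evaluating the impact function at `beta +/- se`
#' and halving the spread (a first-order delta-method equivalent for this
#' monotone function; not a full Monte Carlo).
#'
#' @param tracts tract table with columns `tract_id`, `county_id`,
#'   `population`, `incidence`, `vulnerability_score`.
#' @param exposures data.frame with `tract_id` and `delta_c` (ug/m3,
#'   positive = reduction), or a named numeric vector of reductions.
#' @param crfs list of [crf()] objects; defaults to [default_crfs()].
#' @param pooling `"auto"`, `"fixed"` or `"random"` (see [pool_effects()]).
#' @return data.frame of class `health_impact` with columns `tract_id`,
#'   `county_id`, `delta_c`, `avoided_deaths`, `avoided_deaths_se`, ordered
#'   by ascending `tract_id`; the `pooled` attribute carries the
#'   `pooled_effect` used.
#' @export
impact_assessment <- function(tracts, exposures, crfs = default_crfs(),
                              pooling = c("auto", "fixed", "random")) {
  check_tracts(tracts)
  pooling <- match.arg(pooling)
  if (is.numeric(exposures) && !is.null(names(exposures)))
    exposures <- data.frame(tract_id = names(exposures),
                            delta_c = as.numeric(exposures),
                            stringsAsFactors = FALSE)
  if (!is.data.frame(exposures) || !all(c("tract_id", "delta_c") %in% names(exposures)))
    stop_cb("'exposures' must have columns tract_id and delta_c")
  only_t <- setdiff(tracts$tract_id, exposures$tract_id)
  only_e <- setdiff(exposures$tract_id, tracts$tract_id)
  if (length(only_t) || length(only_e))
    stop_cb("tract/exposure sets differ: missing exposure for {%s}; extra exposure for {%s}",
            paste(only_t, collapse = ", "), paste(only_e, collapse = ", "))
  pooled <- pool_effects(crfs, pooling)

  ord <- order(tracts$tract_id)
  tr <- tracts[ord, , drop = FALSE]
  dc <- exposures$delta_c[match(tr$tract_id, exposures$tract_id)]
  deaths <- avoided_cases(tr$incidence, tr$population, pooled$beta, dc)
  hi <- avoided_cases(tr$incidence, tr$population, pooled$beta + pooled$se, dc)
  lo <- avoided_cases(tr$incidence, tr$population, pooled$beta - pooled$se, dc)
  out <- data.frame(tract_id = tr$tract_id, county_id = tr$county_id,
                    delta_c = dc, avoided_deaths = deaths,
                    avoided_deaths_se = abs(hi - lo) / 2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pooled") <- pooled
  class(out) <- c("health_impact", class(out))
  out
}

#' Recover the effect coefficient from an aggregate death count
#'
#' Deterministically inverts the aggregate health impact function: finds the
#' `beta` for which the summed tract-level avoided deaths equal
#' `total_avoided`, by monotone root bracketing.  Used for parameter
#' recovery on synthetic regions with a known coefficient.
#'
#' @param total_avoided aggregate avoided deaths per year.
#' @param tracts tract table.
#' @param exposures as in [impact_assessment()].
#' @param interval search interval for beta (per ug/m3).
#' @return estimated beta (per ug/m3), to ~1e-12 absolute tolerance.
#' @export
infer_beta <- function(total_avoided, tracts, exposures,
                       interval = c(1e-8, 1)) {
  check_tracts(tracts)
  if (is.numeric(exposures) && !is.null(names(exposures)))
    exposures <- data.frame(tract_id = names(exposures),
                            delta_c = as.numeric(exposures),
                            stringsAsFactors = FALSE)
  dc <- exposures$delta_c[match(tracts$tract_id, exposures$tract_id)]
  f <- function(b) sum(avoided_cases(tracts$incidence, tracts$population, b, dc)) -
    total_avoided
  uniroot(f, interval, tol = 1e-14)$root
}
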