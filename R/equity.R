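# Environmental-justice assessment: disadvantaged-community classification,
# Lorenz curves over vulnerability-ranked tracts, the Suits Index, county
# decomposition, scenario comparison, and benefit dispersity.

#' Classify disadvantaged communities
#'
#' A census tract is a disadvantaged community (DAC) when its vulnerability
#' score places it in the final quartile of the 0-100 screening ranking,
#' i.e. score >= 75 (CalEnviroScreen-style rule).
#'
#' @param score vulnerability score(s) in \[0, 100\].
#' @param threshold classification threshold (default 75).
#' @return logical vector.
#' @export
classify_dac <- function(score, threshold = 75) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100))
    stop_cb("'score' must lie in [0, 100]")
  score >= threshold
}

#' Lorenz curve of benefits over vulnerability-ranked tracts
#'
#' Tracts are sorted by ascending vulnerability score (ties broken by
#' ascending `tract_id`, for determinism); the curve accumulates population
#' share on x and benefit share on y, starting at (0, 0).  Points on the
#' y = x proportionality line indicate benefits distributed exactly in
#' proportion to population.
#'
#' Negative tract benefits are retained as signed increments (the curve may
#' locally decrease and the Suits Index may leave \[-1, 1\]); the result is
#' flagged via `has_negative`.
#'
#' @param tracts tract table.
#' @param benefits per-tract benefits (deaths/yr or USD/yr); named vector
#'   matched by `tract_id`, or unnamed in `tracts` row order.  Total must be
#'   nonzero.
#' @return object of class `lorenz_curve`: list with `x`, `y` (length
#'   n+1, first point (0,0)), `tract_id` (sorted order), `total_benefit`,
#'   `has_negative`.
#' @export
lorenz_curve <- function(tracts, benefits) {
  check_tracts(tracts)
  if (!is.null(names(benefits))) {
    miss <- setdiff(tracts$tract_id, names(benefits))
    if (length(miss))
      stop_cb("'benefits' missing tract(s): %s", paste(miss, collapse = ", "))
    benefits <- as.numeric(benefits[tracts$tract_id])
  } else if (length(benefits) != nrow(tracts)) {
    stop_cb("'benefits' length %d does not match %d tracts",
            length(benefits), nrow(tracts))
  }
  total <- sum(benefits)
  if (total == 0)
    stop_cb("total benefit is zero: Lorenz curve undefined")
  ord <- order(tracts$vulnerability_score, tracts$tract_id)
  pop <- tracts$population[ord]
  ben <- benefits[ord]
  structure(list(
    x = c(0, cumsum(pop) / sum(pop)),
    y = c(0, cumsum(ben) / total),
    tract_id = tracts$tract_id[ord],
    total_benefit = total,
    has_negative = any(ben < 0)
  ), class = "lorenz_curve")
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("Lorenz curve over %d tracts (total benefit %.6g%s)\n",
              length(x$tract_id), x$total_benefit,
              if (x$has_negative) ", contains negative increments" else ""))
  invisible(x)
}

#' Suits Index of a benefit distribution
#'
#' `S = (K - L) / K` with `K = 0.5` the area under the proportionality line
#' and `L` the trapezoid area under the (piecewise-linear, discrete) Lorenz
#' curve.  `S = 0` for a proportional distribution; `S > 0` when benefits
#' concentrate in high-vulnerability (disadvantaged) tracts, `S < 0` when
#' they favor low-vulnerability tracts; `S` lies in \[-1, 1\] when all
#' benefit increments are nonnegative.
#'
#' @param x a `lorenz_curve`, or a tract table (then `benefits` must be
#'   given and the curve is built first).
#' @param benefits per-tract benefits when `x` is a tract table.
#' @param scope label recorded in the result (e.g. `"state"` or a county
#'   id).
#' @return object of class `suits_result`: list with `suits_index`,
#'   `n_tracts`, `total_benefit`, `scope`, `has_negative`.
#' @examples
#' tr <- data.frame(tract_id = c("a", "b"), county_id = "c",
#'                  population = c(1, 1), incidence = 0.008,
#'                  vulnerability_score = c(10, 90))
#' suits_index(tr, benefits = c(0, 5))$suits_index  # +0.5
#' @export
suits_index <- function(x, benefits = NULL, scope = "state") {
  curve <- if (inherits(x, "lorenz_curve")) x else lorenz_curve(x, benefits)
  L <- sum(diff(curve$x) * (head(curve$y, -1) + tail(curve$y, -1)) / 2)
  K <- 0.5
  structure(list(suits_index = (K - L) / K,
                 n_tracts = length(curve$tract_id),
                 total_benefit = curve$total_benefit,
                 scope = scope,
                 has_negative = curve$has_negative),
            class = "suits_result")
}

#' @export
print.suits_result <- function(x, ...) {
  cat(sprintf("Suits Index [%s]: %.4f (%d tracts, total benefit %.6g)%s\n",
              x$scope, x$suits_index, x$n_tracts, x$total_benefit,
              if (x$has_negative) "  [negative increments: [-1,1] bound not guaranteed]" else ""))
  invisible(x)
}

#' County-level Suits Index decomposition
#'
#' Restricts the benefit distribution to each county, renormalizing
#' population and benefit shares within the county, so each county's index
#' measures within-county progressivity only (a county can be negative while
#' the statewide index is positive).  Counties whose total benefit is zero
#' get `NA` and a flag.
#'
#' @param tracts tract table.
#' @param benefits per-tract benefits (named by tract_id, or in row order).
#' @return data.frame with columns `county_id`, `suits_index`, `n_tracts`,
#'   `total_benefit`, `zero_benefit`, `has_negative`, ordered by ascending
#'   `county_id`.
#' @export
suits_by_county <- function(tracts, benefits) {
  check_tracts(tracts)
  if (is.null(names(benefits))) {
    if (length(benefits) != nrow(tracts))
      stop_cb("'benefits' length %d does not match %d tracts",
              length(benefits), nrow(tracts))
    names(benefits) <- tracts$tract_id
  }
  counties <- sort(unique(tracts$county_id))
  rows <- lapply(counties, function(cid) {
    sub <- tracts[tracts$county_id == cid, , drop = FALSE]
    ben <- benefits[sub$tract_id]
    if (sum(ben) == 0) {
      data.frame(county_id = cid, suits_index = NA_real_,
                 n_tracts = nrow(sub), total_benefit = 0,
                 zero_benefit = TRUE, has_negative = any(ben < 0),
                 stringsAsFactors = FALSE)
    } else {
      s <- suits_index(sub, benefits = ben, scope = cid)
      data.frame(county_id = cid, suits_index = s$suits_index,
                 n_tracts = s$n_tracts, total_benefit = s$total_benefit,
                 zero_benefit = FALSE, has_negative = s$has_negative,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-county equity difference between two scenarios
#'
#' Elementwise differences A - B of county avoided deaths and county Suits
#' Indices.  A negative Suits delta means scenario B allocates benefits
#' more toward disadvantaged communities than scenario A in that county.
#'
#' @param a,b data.frames with columns `county_id`, `avoided_deaths`,
#'   `suits_index` (one row per county; same county sets).
#' @return data.frame with `county_id`, `delta_avoided_deaths`,
#'   `delta_suits`, ordered by ascending `county_id`.
#' @export
scenario_delta_equity <- function(a, b) {
  req <- c("county_id", "avoided_deaths", "suits_index")
  for (nm in list(a, b))
    if (!is.data.frame(nm) || !all(req %in% names(nm)))
      stop_cb("inputs must have columns %s", paste(req, collapse = ", "))
  only_a <- setdiff(a$county_id, b$county_id)
  only_b <- setdiff(b$county_id, a$county_id)
  if (length(only_a) || length(only_b))
    stop_cb("county sets differ: only in A {%s}; only in B {%s}",
            paste(only_a, collapse = ", "), paste(only_b, collapse = ", "))
  ids <- sort(unique(a$county_id))
  ia <- match(ids, a$county_id); ib <- match(ids, b$county_id)
  data.frame(county_id = ids,
             delta_avoided_deaths = a$avoided_deaths[ia] - b$avoided_deaths[ib],
             delta_suits = a$suits_index[ia] - b$suits_index[ib],
             stringsAsFactors = FALSE)
}

#' Dispersity of the tract benefit distribution
#'
#' Min-max normalizes the per-tract benefits to \[0, 1\] and returns the
#' population (divisor n) standard deviation: a scale-free measure of how
#' unevenly benefits spread across tracts (smaller sigma = more uniform).
#' Constant benefits normalize to an all-zero vector by convention, giving
#' sigma = 0.
#'
#' @param benefits per-tract benefits (length >= 2).
#' @return list with `sigma` and `n`.
#' @examples
#' dispersity(c(0, 1, 2))$sigma  # 0.40825
#' @export
dispersity <- function(benefits) {
  if (length(benefits) < 2L) stop_cb("dispersity requires >= 2 tracts")
  if (any(!is.finite(benefits))) stop_cb("'benefits' must be finite")
  rng <- range(benefits)
  z <- if (rng[1] == rng[2]) rep(0, length(benefits)) else
    (benefits - rng[1]) / (rng[2] - rng[1])
  list(sigma = sqrt(mean((z - mean(z))^2)), n = length(benefits))
}
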