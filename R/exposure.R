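# Exposure aggregation: gridded annual-mean PM2.5 to census tracts.

#' Aggregate a gridded concentration field to census tracts
#'
#' Computes the weighted mean concentration for each tract from a gridded
#' annual-mean PM2.5 field and an explicit tract-to-cell weight mapping
#' (the bridge between a chemical-transport-model grid and tract-level
#' health assessment).  No geometric overlay is performed here; the weights
#' are an input, typically produced by [generate_region()] or an external
#' GIS step.
#'
#' @param field numeric matrix of annual-mean concentrations (ug/m3),
#'   row-major, indexed 0-based by the weight table.
#' @param weights data.frame with columns `tract_id`, `row`, `col` (0-based
#'   cell indices) and `weight`.  Weights must sum to 1 (within 1e-6) per
#'   tract.
#' @return named numeric vector of per-tract concentrations (ug/m3), in
#'   ascending `tract_id` order.
#' @examples
#' f <- matrix(c(8, 12), 1, 2)
#' w <- data.frame(tract_id = "T1", row = 0L, col = 0:1, weight = 0.5)
#' aggregate_to_tracts(f, w)  # 10
#' @export
aggregate_to_tracts <- function(field, weights) {
  if (!is.matrix(field) || !is.numeric(field))
    stop_cb("'field' must be a numeric matrix")
  if (any(!is.finite(field))) stop_cb("'field' contains non-finite values")
  req <- c("tract_id", "row", "col", "weight")
  if (!is.data.frame(weights) || !all(req %in% names(weights)))
    stop_cb("'weights' must have columns %s", paste(req, collapse = ", "))
  nr <- nrow(field); nc <- ncol(field)
  bad <- weights$row < 0 | weights$row >= nr | weights$col < 0 | weights$col >= nc
  if (any(bad))
    stop_cb("cell index out of range for tract(s): %s (grid is %d x %d)",
            paste(unique(weights$tract_id[bad]), collapse = ", "), nr, nc)
  sums <- tapply(weights$weight, weights$tract_id, sum)
  off <- abs(sums - 1) > 1e-6
  if (any(off))
    stop_cb("tract weight sums differ from 1 by more than 1e-6: %s",
            paste(sprintf("%s (%.8g)", names(sums)[off], sums[off]), collapse = ", "))
  cellval <- field[cbind(weights$row + 1L, weights$col + 1L)]
  agg <- tapply(weights$weight * cellval, weights$tract_id, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(names(out))]
}

#' Concentration change between a reference and a scenario
#'
#' Per-tract concentration reduction `delta_c = reference - scenario`, so a
#' positive value is an air-quality improvement.  Local worsening (scenario
#' above reference) is preserved as a negative value, never clipped.
#'
#' @param reference,scenario named numeric vectors of per-tract
#'   concentrations (ug/m3); names are tract ids and the two sets must match.
#' @return data.frame with columns `tract_id` and `delta_c` (ug/m3, positive
#'   = reduction), in ascending `tract_id` order.
#' @export
scenario_delta <- function(reference, scenario) {
  if (is.null(names(reference)) || is.null(names(scenario)))
    stop_cb("'reference' and 'scenario' must be named by tract_id")
  only_ref <- setdiff(names(reference), names(scenario))
  only_sce <- setdiff(names(scenario), names(reference))
  if (length(only_ref) || length(only_sce))
    stop_cb("tract sets differ: only in reference {%s}; only in scenario {%s}",
            paste(only_ref, collapse = ", "), paste(only_sce, collapse = ", "))
  ids <- sort(names(reference))
  data.frame(tract_id = ids,
             delta_c = as.numeric(reference[ids] - scenario[ids]),
             stringsAsFactors = FALSE)
}

#' Population-weighted mean of a per-tract quantity
#'
#' `sum(pop * value) / sum(pop)` over tracts, the exposure summary used to
#' compare scenarios (e.g. population-weighted annual-mean PM2.5).
#'
#' @param values per-tract numeric vector; if named, matched to
#'   `tracts$tract_id`, otherwise taken in row order.
#' @param tracts tract table (see [check_tracts()] columns).
#' @return scalar, in the units of `values`.
#' @export
population_weighted_mean <- function(values, tracts) {
  check_tracts(tracts)
  if (!is.null(names(values))) {
    miss <- setdiff(tracts$tract_id, names(values))
    if (length(miss))
      stop_cb("'values' missing tract(s): %s", paste(miss, collapse = ", "))
    values <- values[tracts$tract_id]
  } else if (length(values) != nrow(tracts)) {
    stop_cb("'values' length %d does not match %d tracts",
            length(values), nrow(tracts))
  }
  sum(tracts$population * values) / sum(tracts$population)
}
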