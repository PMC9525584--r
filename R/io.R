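# File formats: tract tables, gridded fields as CSV (row,col,value with
# 0-based row-major indices), weight mappings, and the JSON pipeline config.
# Numeric values are written in full precision so read-back reproduces the
# in-memory region exactly.

# -- Gridded fields ----------------------------------------------------------

write_field_csv <- function(field, path) {
  nr <- nrow(field); nc <- ncol(field)
  idx <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  df <- data.frame(row = idx$row, col = idx$col,
                   value = as.numeric(t(field)))
  write_csv_plain(df, path)
}

read_field_csv <- function(path) {
  df <- read_csv_plain(path, colClasses = c("integer", "integer", "numeric"))
  if (!all(c("row", "col", "value") %in% names(df)))
    stop_cb("grid file '%s' must have columns row,col,value", path)
  nr <- max(df$row) + 1L; nc <- max(df$col) + 1L
  m <- matrix(NA_real_, nr, nc)
  m[cbind(df$row + 1L, df$col + 1L)] <- df$value
  if (anyNA(m)) stop_cb("grid file '%s' does not cover every cell", path)
  m
}

# -- Tract and weight tables -------------------------------------------------

# External column name for incidence follows the on-disk interface.
write_tracts_csv <- function(tracts, path) {
  df <- data.frame(tract_id = tracts$tract_id, county_id = tracts$county_id,
                   population = tracts$population,
                   incidence_per_person_year = tracts$incidence,
                   vulnerability_score = tracts$vulnerability_score,
                   stringsAsFactors = FALSE)
  write_csv_plain(df, path)
}

read_tracts_csv <- function(path) {
  df <- read_csv_plain(path)
  req <- c("tract_id", "county_id", "population", "incidence_per_person_year",
           "vulnerability_score")
  if (!all(req %in% names(df)))
    stop_cb("tract file '%s' must have columns %s", path,
            paste(req, collapse = ", "))
  out <- data.frame(tract_id = as.character(df$tract_id),
                    county_id = as.character(df$county_id),
                    population = df$population,
                    incidence = df$incidence_per_person_year,
                    vulnerability_score = df$vulnerability_score,
                    stringsAsFactors = FALSE)
  check_tracts(out)
}

read_weights_csv <- function(path) {
  df <- read_csv_plain(path)
  if (!all(c("tract_id", "row", "col", "weight") %in% names(df)))
    stop_cb("weight file '%s' must have columns tract_id,row,col,weight", path)
  df$tract_id <- as.character(df$tract_id)
  df
}

# -- Region write / read -----------------------------------------------------

#' Write a synthetic region as the pipeline's canonical input files
#'
#' Emits the tract CSV, the baseline concentration grid, one reduction grid
#' per scenario, the tract/cell weight mapping, and a `config.json` that
#' [run_pipeline()] can consume directly.  All numbers are written in full
#' precision so [read_region()] reproduces the region exactly.
#'
#' @param region a `synthetic_region`.
#' @param directory output directory (created if absent).
#' @return invisibly, a manifest data.frame with columns `file`, `kind`,
#'   `scenario`.
#' @export
write_region <- function(region, directory) {
  validate_region(region)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_cb("cannot create directory '%s'", directory)
  p <- function(f) file.path(directory, f)

  write_tracts_csv(region$tracts, p("tracts.csv"))
  write_csv_plain(region$weights, p("weights.csv"))
  write_field_csv(region$baseline_field, p("baseline_pm25.csv"))
  manifest <- data.frame(file = c("tracts.csv", "weights.csv", "baseline_pm25.csv"),
                         kind = c("tracts", "weights", "baseline_field"),
                         scenario = NA_character_, stringsAsFactors = FALSE)
  scen <- list()
  for (nm in names(region$scenario_deltas)) {
    f <- paste0("delta_", nm, ".csv")
    write_field_csv(region$scenario_deltas[[nm]], p(f))
    manifest <- rbind(manifest,
                      data.frame(file = f, kind = "scenario_field",
                                 scenario = nm, stringsAsFactors = FALSE))
    scen[[length(scen) + 1L]] <-
      list(name = nm, field = f, cost = region$scenario_costs[[nm]])
  }
  config <- list(tracts = "tracts.csv", weights = "weights.csv",
                 baseline_field = "baseline_pm25.csv",
                 scenario_field_type = "reduction",
                 scenarios = scen,
                 pooling = "auto", vsl = 9.7e6, dac_threshold = 75,
                 meta = region$meta[setdiff(names(region$meta), "spec")],
                 seed = region$meta$spec$seed %||% region$meta$seed)
  jsonlite::write_json(config, p("config.json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  manifest <- rbind(manifest,
                    data.frame(file = "config.json", kind = "config",
                               scenario = NA_character_, stringsAsFactors = FALSE))
  invisible(manifest)
}

#' Read a region back from files written by [write_region()]
#'
#' @param directory directory containing `config.json` and the files it
#'   references.
#' @return a `synthetic_region` (with `meta` restricted to what the config
#'   records).
#' @export
read_region <- function(directory) {
  cfg <- read_config(file.path(directory, "config.json"))
  tracts <- read_tracts_csv(cfg$tracts)
  weights <- read_weights_csv(cfg$weights)
  baseline <- read_field_csv(cfg$baseline_field)
  deltas <- list(); costs <- numeric(0)
  for (sc in cfg$scenarios) {
    fld <- read_field_csv(sc$field)
    if (identical(cfg$scenario_field_type, "concentration"))
      fld <- baseline - fld
    deltas[[sc$name]] <- fld
    costs[[sc$name]] <- sc$cost
  }
  meta <- cfg$meta %||% list()
  meta$seed <- cfg$seed
  region <- structure(list(tracts = tracts, weights = weights,
                           baseline_field = baseline,
                           scenario_deltas = deltas, scenario_costs = costs,
                           meta = meta),
                      class = "synthetic_region")
  validate_region(region)
  region
}

# -- Pipeline config ---------------------------------------------------------

#' Read and validate a pipeline configuration
#'
#' The config is a single JSON file; relative paths are resolved against
#' the config file's directory.  Required keys: `tracts`, `weights`,
#' `baseline_field`, `scenarios` (each with `name`, `field`, `cost`).
#' Optional: `scenario_field_type` (`"reduction"`, the default, means the
#' scenario grids are already concentration reductions; `"concentration"`
#' means they are scenario concentrations to subtract from the baseline),
#' `crfs` (list of concentration-response definitions; default
#' [default_crfs()]), `pooling` (`"auto"`), `vsl` (9.7e6), `dac_threshold`
#' (75), `compare` (two scenario names).
#'
#' @param path path to the JSON config.
#' @return object of class `pipeline_config` (a named list with absolute
#'   paths).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_cb("config file '%s' not found", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  pipeline_config(cfg, base_dir = dirname(normalizePath(path)))
}

#' Build a pipeline configuration from a list
#'
#' @param cfg named list (see [read_config()] for keys).
#' @param base_dir directory against which relative input paths resolve.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cfg, base_dir = ".") {
  for (key in c("tracts", "weights", "baseline_field", "scenarios"))
    if (is.null(cfg[[key]])) stop_cb("config is missing required key '%s'", key)
  resolve <- function(f)
    if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base_dir, f)
  for (key in c("tracts", "weights", "baseline_field")) {
    cfg[[key]] <- resolve(cfg[[key]])
    if (!file.exists(cfg[[key]]))
      stop_cb("config input '%s' does not exist: %s", key, cfg[[key]])
  }
  nms <- vapply(cfg$scenarios, function(s) s$name %||% NA_character_, character(1))
  if (anyNA(nms) || anyDuplicated(nms))
    stop_cb("every scenario needs a unique 'name'")
  cfg$scenarios <- lapply(cfg$scenarios, function(s) {
    if (is.null(s$field) || is.null(s$cost))
      stop_cb("scenario '%s' needs 'field' and 'cost'", s$name)
    s$field <- resolve(s$field)
    if (!file.exists(s$field))
      stop_cb("scenario '%s' field file does not exist: %s", s$name, s$field)
    s
  })
  cfg$scenario_field_type <- cfg$scenario_field_type %||% "reduction"
  if (!cfg$scenario_field_type %in% c("reduction", "concentration"))
    stop_cb("'scenario_field_type' must be 'reduction' or 'concentration'")
  cfg$pooling <- cfg$pooling %||% "auto"
  if (!cfg$pooling %in% c("auto", "fixed", "random"))
    stop_cb("'pooling' must be auto, fixed or random")
  cfg$vsl <- cfg$vsl %||% 9.7e6
  check_positive(cfg$vsl, "vsl")
  cfg$dac_threshold <- cfg$dac_threshold %||% 75
  if (!is.null(cfg$compare)) {
    cmp <- unlist(cfg$compare)
    if (length(cmp) != 2L || !all(cmp %in% nms))
      stop_cb("config 'compare' must name two known scenarios (got: %s; known: %s)",
              paste(cmp, collapse = ", "), paste(nms, collapse = ", "))
  }
  cfg$crf_objects <- if (is.null(cfg$crfs)) default_crfs() else
    lapply(cfg$crfs, function(cc)
      crf(name = cc$name, beta = cc$beta, se = cc$se,
          rr_per_10ug = cc$rr_per_10ug, source = cc$source %||% ""))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
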