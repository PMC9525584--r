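# Internal helpers shared across modules.

# Validation -----------------------------------------------------------------

stop_cb <- function(fmt, ..., stage = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(stage)) msg <- paste0("[", stage, "] ", msg)
  stop(msg, call. = FALSE)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_cb("'%s' must be a single non-missing number", name)
  if (finite && !is.finite(x))
    stop_cb("'%s' must be finite", name)
  invisible(x)
}

check_positive <- function(x, name) {
  check_scalar_number(x, name)
  if (x <= 0) stop_cb("'%s' must be > 0 (got %g)", name, x)
  invisible(x)
}

check_count <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 1 || x != floor(x)) stop_cb("'%s' must be a positive integer (got %g)", name, x)
  invisible(as.integer(x))
}

check_tracts <- function(tracts) {
  req <- c("tract_id", "county_id", "population", "incidence", "vulnerability_score")
  if (!is.data.frame(tracts) || !all(req %in% names(tracts)))
    stop_cb("tract table must be a data.frame with columns %s",
            paste(req, collapse = ", "))
  if (nrow(tracts) == 0L) stop_cb("tract table is empty")
  if (anyDuplicated(tracts$tract_id)) stop_cb("duplicated tract_id in tract table")
  if (any(!is.finite(tracts$population)) || any(tracts$population <= 0))
    stop_cb("all tract populations must be finite and > 0")
  if (any(!is.finite(tracts$incidence)) || any(tracts$incidence < 0))
    stop_cb("all tract incidence rates must be finite and >= 0")
  sc <- tracts$vulnerability_score
  if (any(!is.finite(sc)) || any(sc < 0) || any(sc > 100))
    stop_cb("vulnerability scores must lie in [0, 100]")
  invisible(tracts)
}

# Deterministic sub-streams --------------------------------------------------

# One user-facing integer seed governs all draws.  Each generation stage uses
# its own sub-seed so that adding a stage never perturbs the draws of another.
# Scheme: sub_seed(seed, k) = (seed * 48271 + 7919 * k) mod (2^31 - 1),
# with k the fixed index of the named stage below.
.cb_streams <- c(layout = 1L, weights = 2L, population = 3L, incidence = 4L,
                 vulnerability = 5L, baseline = 6L, scenario = 7L, jitter = 8L)

sub_seed <- function(seed, stream, offset = 0L) {
  k <- .cb_streams[[stream]] + offset
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 7919 * k) %% 2147483647)
}

# Number formatting ----------------------------------------------------------

# Full-precision decimal text: round-trips IEEE doubles exactly.
fmt_full <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.1f", x), sprintf("%.17g", x))
}

# Reporting precision for pipeline CSV output (6 significant digits).
fmt_sig6 <- function(x) sprintf("%.6g", x)

# Deterministic CSV writer: no locale-dependent formatting, LF line ends.
write_csv_plain <- function(df, path, fmt = fmt_full) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

read_csv_plain <- function(path, colClasses = NA) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = colClasses)
}

# Rolling polynomial hash of a character vector, for the run manifest's
# config hash (audit fingerprint, not cryptographic).
content_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
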