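#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom grDevices png dev.off
#' @importFrom graphics hist
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards, so generators are reproducible without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one master seed fans out to per-stage /
# per-participant seeds. Kept below 2^31 - 1 (R integer range).
sub_seed <- function(master, k) {
  as.integer(((as.numeric(master) %% 1e6) * 1009 + (as.numeric(k) %% 1e6) * 9973 + 17) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

# Survey start used when rendering ISO-8601 timestamps (a Friday, matching a
# Friday + Saturday survey pair); internal times are seconds from this origin.
survey_origin <- function() as.POSIXct("2021-06-04 00:00:00", tz = "UTC")

iso_time <- function(time_s) {
  format(survey_origin() + time_s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso_time <- function(x) {
  as.numeric(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) -
    as.numeric(survey_origin())
}
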