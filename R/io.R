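#' Write a spike raster to CSV
#'
#' Format: a metadata line `# n_units=<int> duration_s=<float>`, a header
#' `unit_id,time_s`, then one row per spike.
#'
#' @param raster a [spike_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_units=%d duration_s=%.10g",
                     raster$n_units, raster$duration_s), con)
  writeLines("unit_id,time_s", con)
  for (i in seq_len(raster$n_units)) {
    s <- raster$spikes[[i]]
    if (length(s)) {
      writeLines(sprintf("%d,%.10g", i, s), con)
    }
  }
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' Inverse of [write_raster()]; round-trips up to float formatting. Parse
#' errors name the offending line.
#'
#' @param path input file path.
#' @return a [spike_raster()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# *n_units=", lines[1L])) {
    stop("line 1: expected metadata header '# n_units=<int> duration_s=<float>'",
         call. = FALSE)
  }
  meta <- regmatches(lines[1L],
                     regexec("n_units=([0-9]+) +duration_s=([0-9.eE+-]+)",
                             lines[1L]))[[1L]]
  if (length(meta) != 3L) {
    stop("line 1: malformed metadata header", call. = FALSE)
  }
  n_units <- as.integer(meta[2L])
  duration <- as.numeric(meta[3L])
  if (length(lines) < 2L || trimws(lines[2L]) != "unit_id,time_s") {
    stop("line 2: expected header 'unit_id,time_s'", call. = FALSE)
  }
  spikes <- rep(list(numeric(0)), n_units)
  body <- lines[-(1:2)]
  body_keep <- nzchar(trimws(body))
  if (any(body_keep)) {
    rows <- strsplit(body[body_keep], ",", fixed = TRUE)
    lineno <- (which(body_keep)) + 2L
    bad <- which(lengths(rows) != 2L)
    if (length(bad)) {
      stop(sprintf("line %d: expected two comma-separated fields",
                   lineno[bad[1L]]), call. = FALSE)
    }
    unit <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1L)))
    tm <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
    bad <- which(is.na(unit) | is.na(tm))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric field", lineno[bad[1L]]),
           call. = FALSE)
    }
    bad <- which(unit < 1L | unit > n_units)
    if (length(bad)) {
      stop(sprintf("line %d: unit_id out of range 1..%d",
                   lineno[bad[1L]], n_units), call. = FALSE)
    }
    for (i in seq_len(n_units)) {
      idx <- which(unit == i)
      s <- tm[idx]
      if (length(s) && is.unsorted(s, strictly = TRUE)) {
        j <- idx[which(diff(s) <= 0)[1L] + 1L]
        stop(sprintf("line %d: spike times for unit %d not strictly increasing",
                     lineno[j], i), call. = FALSE)
      }
      spikes[[i]] <- s
    }
  }
  spike_raster(spikes, duration)
}

#' Write a hypnogram to CSV
#'
#' Format: header `state,start_s,end_s`, one row per episode, states exactly
#' `WK`, `SWS` or `REM`.
#'
#' @param hyp a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("state,start_s,end_s", con)
  writeLines(sprintf("%s,%.10g,%.10g", hyp$state, hyp$start_s, hyp$end_s), con)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Inverse of [write_hypnogram()]. Unknown state labels (e.g. "NREM") and
#' malformed rows raise a parse error naming the line.
#'
#' @param path input file path.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1L]) != "state,start_s,end_s") {
    stop("line 1: expected header 'state,start_s,end_s'", call. = FALSE)
  }
  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  if (!any(keep)) stop("hypnogram file has no episodes", call. = FALSE)
  rows <- strsplit(body[keep], ",", fixed = TRUE)
  lineno <- which(keep) + 1L
  bad <- which(lengths(rows) != 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected three comma-separated fields",
                 lineno[bad[1L]]), call. = FALSE)
  }
  st <- vapply(rows, `[`, "", 1L)
  bad <- which(!st %in% c("WK", "SWS", "REM"))
  if (length(bad)) {
    stop(sprintf("line %d: unknown state label '%s'",
                 lineno[bad[1L]], st[bad[1L]]), call. = FALSE)
  }
  a <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  b <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  bad <- which(is.na(a) | is.na(b))
  if (length(bad)) {
    stop(sprintf("line %d: non-numeric episode bounds", lineno[bad[1L]]),
         call. = FALSE)
  }
  hypnogram(st, a, b)
}
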