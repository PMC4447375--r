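#' Hypnogram container
#'
#' An ordered, contiguous, non-overlapping sequence of behavioral-state
#' episodes over \{WK, SWS, REM\}. Invariants enforced: episodes sorted by
#' start, each start equals the previous end, positive durations, no two
#' consecutive episodes share a state, and every REM episode is immediately
#' preceded by an SWS episode.
#'
#' @param state character vector of states, each one of "WK", "SWS", "REM".
#' @param start_s,end_s episode bounds in seconds.
#' @return a `data.frame` of class `hypnogram` with columns `state`,
#'   `start_s`, `end_s`.
#' @export
hypnogram <- function(state, start_s, end_s) {
  state <- as.character(state)
  if (!all(state %in% c("WK", "SWS", "REM"))) {
    stop("states must be one of WK, SWS, REM", call. = FALSE)
  }
  n <- length(state)
  stopifnot(length(start_s) == n, length(end_s) == n, n >= 1L)
  if (any(end_s <= start_s)) stop("episodes must have end_s > start_s",
                                  call. = FALSE)
  if (is.unsorted(start_s, strictly = TRUE) && n > 1L) {
    stop("episodes must be sorted by start time", call. = FALSE)
  }
  if (n > 1L) {
    if (any(abs(start_s[-1L] - end_s[-n]) > 1e-9)) {
      stop("episodes must be contiguous (each start equals previous end)",
           call. = FALSE)
    }
    if (any(state[-1L] == state[-n])) {
      stop("consecutive episodes must not share a state", call. = FALSE)
    }
  }
  rem_idx <- which(state == "REM")
  bad <- rem_idx[rem_idx == 1L | state[pmax(rem_idx - 1L, 1L)] != "SWS"]
  if (length(bad)) {
    stop("every REM episode must be immediately preceded by SWS",
         call. = FALSE)
  }
  structure(data.frame(state = state, start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s)),
            class = c("hypnogram", "data.frame"))
}

#' Default episode-duration parameters for the hypnogram generator
#'
#' Episode durations are log-normal. SWS parameters reproduce a mean episode
#' duration of about 87 s (SD about 47 s); WK parameters are calibrated so
#' that about 91.6% of REM-onset-to-REM-onset intervals are shorter than 30
#' minutes; REM durations use a typical rat mean of 100 s (SD 50 s).
#'
#' @param wk_meanlog,wk_sdlog log-normal parameters of WK episode durations.
#' @param sws_meanlog,sws_sdlog log-normal parameters of SWS durations.
#' @param rem_meanlog,rem_sdlog log-normal parameters of REM durations.
#' @return named list of class `hypnogram_params`.
#' @export
hypnogram_params <- function(wk_meanlog = 5.1767, wk_sdlog = 1.6,
                             sws_meanlog = 4.3379, sws_sdlog = 0.5060,
                             rem_meanlog = 4.4936, rem_sdlog = 0.4724) {
  p <- list(wk_meanlog = wk_meanlog, wk_sdlog = wk_sdlog,
            sws_meanlog = sws_meanlog, sws_sdlog = sws_sdlog,
            rem_meanlog = rem_meanlog, rem_sdlog = rem_sdlog)
  for (nm in c("wk_sdlog", "sws_sdlog", "rem_sdlog")) {
    .check_positive(p[[nm]], nm)
  }
  structure(p, class = "hypnogram_params")
}

#' Generate a synthetic hypnogram
#'
#' Produces `n_cycles` WK -> SWS -> REM cycles with log-normal episode
#' durations. With default parameters the mean SWS episode is about 87 s and
#' about 91.6% of intervals between consecutive REM onsets are shorter than
#' 30 minutes, matching rat sleep-architecture statistics.
#'
#' @param n_cycles number of full cycles (>= 1).
#' @param params a [hypnogram_params()].
#' @param seed optional integer seed.
#' @return a [hypnogram()].
#' @export
gen_hypnogram <- function(n_cycles, params = hypnogram_params(), seed = NULL) {
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop("`n_cycles` must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(params, "hypnogram_params"))
  .seed_if_given(seed)
  n_cycles <- as.integer(n_cycles)
  wk <- stats::rlnorm(n_cycles, params$wk_meanlog, params$wk_sdlog)
  sws <- stats::rlnorm(n_cycles, params$sws_meanlog, params$sws_sdlog)
  rem <- stats::rlnorm(n_cycles, params$rem_meanlog, params$rem_sdlog)
  dur <- as.vector(rbind(wk, sws, rem))
  state <- rep(c("WK", "SWS", "REM"), n_cycles)
  end <- cumsum(dur)
  start <- c(0, end[-length(end)])
  hypnogram(state, start, end)
}

#' REM-onset-to-REM-onset intervals
#'
#' @param hyp a [hypnogram()].
#' @return numeric vector of intervals (s) between consecutive REM onsets.
#' @export
rem_onset_intervals <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  onsets <- hyp$start_s[hyp$state == "REM"]
  if (length(onsets) < 2L) return(numeric(0))
  diff(onsets)
}

#' Fraction of REM-to-REM intervals shorter than a threshold
#'
#' @param hyp a [hypnogram()].
#' @param threshold_s threshold in seconds (default 30 minutes).
#' @return scalar fraction in `[0, 1]`.
#' @export
rem_interval_fraction <- function(hyp, threshold_s = 1800) {
  iv <- rem_onset_intervals(hyp)
  if (!length(iv)) return(NA_real_)
  mean(iv < threshold_s)
}

#' Total time per state
#' @param hyp a [hypnogram()].
#' @return named numeric vector of seconds per state.
#' @export
state_durations <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  tapply(hyp$end_s - hyp$start_s, hyp$state, sum)
}
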