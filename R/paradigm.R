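#' Experimental paradigm
#'
#' Describes stimulus timing and image acquisition for a sparse-sampling
#' (silent) fMRI design: stimulus onsets and durations, acquisition-window
#' onsets, the repetition time `TR` between acquisitions, the acquisition
#' window length `TA`, and the integration micro-time step `dt`. Predicted
#' BOLD is sampled once per acquisition at a reference point inside the
#' window (`acq_frac` of `TA` after the window opens; default the midpoint).
#'
#' @param stim_onsets stimulus onset times (s), strictly increasing.
#' @param stim_durations stimulus durations (s), positive, recycled.
#' @param acq_onsets acquisition-window onset times (s).
#' @param TR,TA nominal repetition and acquisition times (s).
#' @param dt integration step (s), in (0, 0.5].
#' @param acq_frac sampling reference point as a fraction of `TA` (default
#'   0.5, the window midpoint).
#' @param duration total simulated duration (s); defaults to the end of the
#'   last acquisition window.
#' @return An object of class `dcm_paradigm` with a `sample_times` field
#'   (`acq_onsets + acq_frac * TA`).
#' @seealso [make_paradigm()] for the study's alternating design.
#' @export
paradigm <- function(stim_onsets, stim_durations, acq_onsets,
                     TR = 16, TA = 5, dt = 0.125, acq_frac = 0.5,
                     duration = NULL) {
  stim_onsets <- as.numeric(stim_onsets)
  stim_durations <- rep_len(as.numeric(stim_durations),
                            length(stim_onsets))
  acq_onsets <- as.numeric(acq_onsets)
  if (length(stim_onsets) && any(diff(stim_onsets) <= 0)) {
    stop("stimulus onsets must be strictly increasing")
  }
  if (length(stim_onsets) && any(stim_durations <= 0)) stop("stimulus durations must be positive")
  if (TR <= 0 || TA <= 0) stop("TR and TA must be positive")
  if (dt <= 0 || dt > 0.5) stop("dt must be in (0, 0.5]")
  if (acq_frac < 0 || acq_frac > 1) stop("acq_frac must be in [0, 1]")
  if (is.null(duration)) duration <- max(acq_onsets) + TA
  sample_times <- acq_onsets + acq_frac * TA
  if (any(acq_onsets < 0) || any(sample_times > duration)) {
    stop("acquisition times must lie within [0, duration]")
  }
  structure(list(stim_onsets = stim_onsets, stim_durations = stim_durations,
                 acq_onsets = acq_onsets, TR = TR, TA = TA, dt = dt,
                 acq_frac = acq_frac, duration = duration,
                 sample_times = sample_times),
            class = "dcm_paradigm")
}

#' @export
print.dcm_paradigm <- function(x, ...) {
  cat(sprintf("<dcm_paradigm> %d acquisitions (TR %gs, TA %gs), %d stimuli, %gs total, dt %gs\n",
              length(x$acq_onsets), x$TR, x$TA, length(x$stim_onsets),
              x$duration, x$dt))
  invisible(x)
}

#' Stimulus input on the integration grid
#'
#' The external input `u(t)` is a unit-amplitude boxcar over each stimulus
#' interval.
#'
#' @param paradigm a `dcm_paradigm`.
#' @param times evaluation times (s); defaults to the integration grid.
#' @return Numeric vector of 0/1 input values.
#' @export
stimulus_input <- function(paradigm, times = seq(0, paradigm$duration, by = paradigm$dt)) {
  u <- numeric(length(times))
  for (k in seq_along(paradigm$stim_onsets)) {
    on <- paradigm$stim_onsets[k]
    u[times >= on & times < on + paradigm$stim_durations[k]] <- 1
  }
  u
}

#' Read and write paradigms
#'
#' Paradigms serialize to a structured-text (YAML) document; the round trip
#' is lossless.
#'
#' @param paradigm a `dcm_paradigm`.
#' @param path file path.
#' @export
write_paradigm <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "dcm_paradigm"))
  yaml::write_yaml(unclass(paradigm), path)
  invisible(path)
}

#' @rdname write_paradigm
#' @export
read_paradigm <- function(path) {
  doc <- yaml::read_yaml(path)
  paradigm(doc$stim_onsets, doc$stim_durations, doc$acq_onsets,
           TR = doc$TR, TA = doc$TA, dt = doc$dt, acq_frac = doc$acq_frac,
           duration = doc$duration)
}
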