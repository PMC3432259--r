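#' Sparse-sampling auditory paradigm
#'
#' Builds the silent (sparse temporal sampling) design: acquisitions every
#' `TR` seconds with acquisition windows of `TA` seconds, and a stimulus of
#' `stim_dur` seconds ending at the onset of every second acquisition, so
#' stimulus deliveries alternate with silent baseline acquisitions and
#' consecutive stimulus onsets are `stim_spacing` seconds apart.
#'
#' @param n_scans number of acquisitions (>= 1).
#' @param TR repetition time (s), default 16.
#' @param TA acquisition time (s), default 5.
#' @param stim_dur stimulus duration (s), default 6.
#' @param stim_spacing interval between consecutive stimulus onsets (s),
#'   default 32 (= 2 TR).
#' @param dt integration step (s), default 0.125.
#' @return A `dcm_paradigm`. With `n_scans = 4` there are 2 stimulus
#'   epochs.
#' @export
make_paradigm <- function(n_scans, TR = 16, TA = 5, stim_dur = 6,
                          stim_spacing = 2 * TR, dt = 0.125) {
  if (n_scans < 1) stop("n_scans must be >= 1")
  if (TR <= 0 || TA <= 0 || stim_dur <= 0 || stim_spacing <= 0) {
    stop("timing parameters must be positive")
  }
  acq_onsets <- (seq_len(n_scans) - 1) * TR
  # a stimulus ends exactly at the onset of every second acquisition
  n_stim <- n_scans %/% 2
  stim_onsets <- if (n_stim >= 1) {
    TR - stim_dur + (seq_len(n_stim) - 1) * stim_spacing
  } else numeric(0)
  if (n_stim >= 1 && any(stim_onsets < 0)) stop("stim_dur exceeds TR")
  paradigm(stim_onsets, rep(stim_dur, length(stim_onsets)), acq_onsets,
           TR = TR, TA = TA, dt = dt)
}

#' Ground-truth parameters of the auditory network
#'
#' Mean parameter values used by the cohort generator: every coupling
#' supported by `spec` is set to its reported group mean (see
#' [reference_connection_stats()]; the four retained STG -> HG couplings
#' are LSTG->LHG 0.0973, LSTG->RHG 0.0801, RSTG->LHG 0.1716, RSTG->RHG
#' 0.1339 Hz), driving input at LSTG 0.1356 and RSTG 0.2551 Hz,
#' self-connections at -0.5 Hz, and default haemodynamics. When `spec`
#' carries modulation or gating support, those entries are set to
#' `b_value`/`d_value`. For a fully connected spec this yields the
#' complete published 12-coupling configuration.
#'
#' @param spec a `dcm_model_spec` over the canonical region set; driving
#'   input must be placed at STG (the only input strengths reported).
#' @param b_value modulation strength (Hz per unit input) applied to every
#'   supported B entry.
#' @param d_value gating strength (Hz per unit activity) applied to every
#'   supported D entry; 0.5 by default, a typical reported magnitude for
#'   non-linear gating.
#' @return A `dcm_params` object.
#' @export
auditory_ground_truth <- function(spec = build_pruned_winner(),
                                  b_value = 0.1, d_value = 0.5) {
  lab <- spec$regions$labels
  stopifnot(identical(lab, auditory_regions()$labels))
  n <- spec$regions$n
  a <- matrix(0, n, n, dimnames = list(lab, lab))
  ref <- reference_connection_stats()
  ref <- ref[ref$type == "coupling", ]
  for (r in seq_len(nrow(ref))) {
    if (spec$a_support[ref$target[r], ref$source[r]] == 1) {
      a[ref$target[r], ref$source[r]] <- ref$mean_hz[r]
    }
  }
  diag(a) <- -0.5
  cmat <- matrix(0, n, ncol(spec$c_support))
  cmat[match("LSTG", lab), 1] <- 0.1356 * spec$c_support[match("LSTG", lab), 1]
  cmat[match("RSTG", lab), 1] <- 0.2551 * spec$c_support[match("RSTG", lab), 1]
  b <- lapply(spec$b_supports, function(s) s * b_value)
  d <- lapply(spec$d_supports, function(s) s * d_value)
  model_parameters(spec, a = a, b = b, c = cmat, d = d)
}

#' Simulate one subject
#'
#' Integrates the model, samples the acquisitions, and adds i.i.d. Gaussian
#' observation noise. Deterministic given the seed.
#'
#' @param spec a `dcm_model_spec`.
#' @param params a `dcm_params`.
#' @param paradigm a `dcm_paradigm`.
#' @param noise_sd absolute noise standard deviation (same units as the
#'   BOLD signal).
#' @param seed RNG seed (mandatory).
#' @param id subject identifier.
#' @return A `dcm_subject`.
#' @export
simulate_subject <- function(spec, params, paradigm, noise_sd, seed,
                             id = "sub1") {
  stopifnot(!missing(seed), noise_sd >= 0)
  clean <- predict_bold(params, paradigm)
  if (is.null(clean)) {
    stop("integration diverged for model '", spec$name, "' (unstable parameters)")
  }
  set.seed(seed)
  noisy <- clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                          nrow(clean), ncol(clean))
  subject_data(id, noisy, paradigm)
}

#' Cohort specification
#'
#' Describes a synthetic group study: the ground-truth model and mean
#' parameters, between-subject variability of the coupling parameters,
#' observation noise as a fraction of each subject's noiseless signal SD,
#' the number of scans, and a mandatory seed.
#'
#' @param spec ground-truth `dcm_model_spec` (default the pruned winner).
#' @param params mean `dcm_params` (default [auditory_ground_truth()]).
#' @param n_subjects number of subjects (default 10).
#' @param sd_between between-subject SD (Hz) applied to the coupling (a),
#'   input (c) and gating (d/b) values, default 0.05.
#' @param noise_sd observation-noise SD as a fraction of the noiseless
#'   sampled-signal SD, default 0.1.
#' @param n_scans scans per subject, default 64.
#' @param dt integration step (s), default 0.125.
#' @param seed RNG seed (mandatory).
#' @return A list of class `dcm_cohort_spec`.
#' @export
cohort_spec <- function(spec = build_pruned_winner(),
                        params = auditory_ground_truth(spec),
                        n_subjects = 10, sd_between = 0.05, noise_sd = 0.1,
                        n_scans = 64, dt = 0.125, seed) {
  stopifnot(!missing(seed), n_subjects >= 1, sd_between >= 0, noise_sd >= 0,
            n_scans >= 1)
  structure(list(spec = spec, params = params, n_subjects = n_subjects,
                 sd_between = sd_between, noise_sd = noise_sd,
                 n_scans = n_scans, dt = dt, seed = as.integer(seed)),
            class = "dcm_cohort_spec")
}

perturb_params <- function(params, sd_between) {
  # jitter every non-zero coupling/input/gating entry; redraw a if unstable
  spec <- params$spec
  n <- spec$regions$n
  for (attempt in 1:20) {
    a <- params$a
    off <- which(spec$a_support == 1 & row(a) != col(a))
    a[off] <- a[off] + stats::rnorm(length(off), sd = sd_between)
    cmat <- params$c
    ci <- which(spec$c_support == 1)
    cmat[ci] <- cmat[ci] + stats::rnorm(length(ci), sd = sd_between)
    b <- params$b
    for (k in seq_along(b)) {
      bi <- which(spec$b_supports[[k]] == 1)
      b[[k]][bi] <- b[[k]][bi] + stats::rnorm(length(bi), sd = sd_between)
    }
    d <- params$d
    for (k in seq_along(d)) {
      di <- which(spec$d_supports[[k]] == 1)
      d[[k]][di] <- d[[k]][di] + stats::rnorm(length(di), sd = sd_between)
    }
    if (all(Re(eigen(a, only.values = TRUE)$values) < 0)) {
      return(model_parameters(spec, a = a, b = b, c = cmat, d = d,
                              hemo = params$hemo))
    }
  }
  stop("could not draw a stable subject-level coupling matrix")
}

#' Simulate a cohort
#'
#' Draws per-subject parameters around the cohort means with the stated
#' between-subject SD (couplings, inputs and gating only; haemodynamics are
#' shared), simulates each subject under the sparse-sampling paradigm, and
#' scales the observation noise to the requested fraction of each subject's
#' noiseless signal SD. The ground truth is returned alongside the data for
#' recovery scoring.
#'
#' @param cs a `dcm_cohort_spec`.
#' @return A list of class `dcm_cohort`: `subjects` (list of
#'   `dcm_subject`), `paradigm`, `truth` (list with the spec, mean params
#'   and per-subject `dcm_params`), `cohort_spec`.
#' @export
simulate_cohort <- function(cs) {
  stopifnot(inherits(cs, "dcm_cohort_spec"))
  par <- make_paradigm(cs$n_scans, dt = cs$dt)
  set.seed(cs$seed)
  subj_seeds <- sample.int(.Machine$integer.max, cs$n_subjects)
  subjects <- vector("list", cs$n_subjects)
  subj_params <- vector("list", cs$n_subjects)
  for (i in seq_len(cs$n_subjects)) {
    set.seed(subj_seeds[i])
    pi_ <- if (cs$sd_between > 0) perturb_params(cs$params, cs$sd_between) else cs$params
    clean <- predict_bold(pi_, par)
    if (is.null(clean)) stop("integration diverged for subject ", i)
    sd_abs <- cs$noise_sd * stats::sd(as.vector(clean))
    subjects[[i]] <- simulate_subject(cs$spec, pi_, par, sd_abs,
                                      seed = subj_seeds[i] %% 2147483646L + 1L,
                                      id = sprintf("sub%02d", i))
    subj_params[[i]] <- pi_
  }
  structure(list(subjects = subjects, paradigm = par,
                 truth = list(spec = cs$spec, mean_params = cs$params,
                              subject_params = subj_params),
                 cohort_spec = cs),
            class = "dcm_cohort")
}

#' @export
print.dcm_cohort <- function(x, ...) {
  cat(sprintf("<dcm_cohort> %d subjects x %d scans from '%s'\n",
              length(x$subjects), ncol(x$subjects[[1]]$bold),
              x$truth$spec$name))
  invisible(x)
}

#' Synthetic log-evidence tables
#'
#' Generates an N x K log-evidence fixture in which every subject gives the
#' winner a fixed free-energy advantage plus standard-normal jitter; used to
#' exercise group BMS without running any inversion.
#'
#' @param N subjects; K models.
#' @param winner_index index of the favoured model (1-based).
#' @param effect_nats free-energy advantage of the winner (>= 0).
#' @param seed RNG seed.
#' @return A `dcm_logev` table.
#' @export
make_logevidence_fixture <- function(N, K, winner_index = 1, effect_nats = 3,
                                     seed = 1L) {
  stopifnot(winner_index >= 1, winner_index <= K, effect_nats >= 0)
  set.seed(seed)
  F <- matrix(stats::rnorm(N * K), N, K)
  F[, winner_index] <- F[, winner_index] + effect_nats
  log_evidence_table(F)
}

#' Write and read a cohort
#'
#' One tab-separated BOLD table per subject plus a structured-text manifest
#' holding the paradigm, seeds, and the ground-truth parameter values.
#' Identical cohort specs produce identical bytes on disk.
#'
#' @param cohort a `dcm_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- file.path(dir, paste0(s$id, "_bold.tsv"))
    write_bold_table(s$bold, s$paradigm$sample_times, files[i])
  }
  write_model_spec(cohort$truth$spec, file.path(dir, "truth_spec.yaml"))
  cs <- cohort$cohort_spec
  manifest <- list(
    subjects = lapply(cohort$subjects, function(s) s$id),
    files = as.list(basename(files)),
    paradigm = unclass(cohort$paradigm),
    seed = cs$seed, n_scans = cs$n_scans, noise_sd = cs$noise_sd,
    sd_between = cs$sd_between,
    truth = list(
      spec_file = "truth_spec.yaml",
      mean_a = mat_to_rows_num(cohort$truth$mean_params$a),
      mean_c = mat_to_rows_num(cohort$truth$mean_params$c),
      subject_a = lapply(cohort$truth$subject_params,
                         function(p) mat_to_rows_num(p$a)),
      subject_c = lapply(cohort$truth$subject_params,
                         function(p) mat_to_rows_num(p$c))
    ))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

mat_to_rows_num <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

#' @rdname write_cohort
#' @return `read_cohort` returns a list with `subjects` (list of
#'   `dcm_subject`), `paradigm` and the manifest.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  pd <- manifest$paradigm
  par <- paradigm(unlist(pd$stim_onsets), unlist(pd$stim_durations),
                  unlist(pd$acq_onsets), TR = pd$TR, TA = pd$TA, dt = pd$dt,
                  acq_frac = pd$acq_frac, duration = pd$duration)
  subjects <- lapply(seq_along(manifest$subjects), function(i) {
    tb <- read_bold_table(file.path(dir, manifest$files[[i]]))
    subject_data(manifest$subjects[[i]], tb$bold, par)
  })
  list(subjects = subjects, paradigm = par, manifest = manifest)
}
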