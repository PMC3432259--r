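#' Neuronal state derivative
#'
#' Evaluates the neuronal state equation
#' `dx/dt = (A + sum_i u_i B_i + sum_j x_j D_j) x + C u` (couplings in Hz).
#' With all gating matrices `D` zero this is the bilinear model; non-zero
#' `D` lets the activity of region `j` gate connection strengths.
#'
#' @param x length-n neuronal state vector (dimensionless activity).
#' @param u length-m external input vector.
#' @param params a `dcm_params` object.
#' @return Length-n derivative vector (Hz).
#' @export
neuronal_derivative <- function(x, u, params) {
  stopifnot(inherits(params, "dcm_params"))
  n <- params$spec$regions$n
  m <- ncol(params$c)
  x <- as.numeric(x); u <- as.numeric(u)
  if (length(x) != n) stop("x must have length ", n)
  if (length(u) != m) stop("u must have length ", m)
  if (any(!is.finite(u))) stop("u must be finite")
  J <- params$a
  for (i in seq_len(m)) J <- J + u[i] * params$b[[i]]
  for (j in seq_len(n)) J <- J + x[j] * params$d[[j]]
  drop(J %*% x + params$c %*% u)
}

#' Haemodynamic state derivative
#'
#' The balloon-Windkessel model: per region,
#' `ds/dt = eps x - kappa s - gamma (f - 1)`, `df/dt = s`,
#' `tau dv/dt = f - v^(1/alpha)`,
#' `tau dq/dt = f (1 - (1-rho)^(1/f))/rho - v^(1/alpha) q / v`.
#' At rest (`x = 0`, `s = 0`, `f = v = q = 1`) the derivative is zero.
#'
#' @param h haemodynamic state: a list or n x 4 matrix with components
#'   `s`, `f`, `v`, `q` (flow, volume and deoxyhaemoglobin normalized to
#'   baseline, all positive).
#' @param x length-n neuronal state.
#' @param params a `dcm_params` object.
#' @return A list with derivative components `s`, `f`, `v`, `q`.
#' @export
hemodynamic_derivative <- function(h, x, params) {
  stopifnot(inherits(params, "dcm_params"))
  h <- as_hemo_state(h, params$spec$regions$n)
  if (any(h$f <= 0) || any(h$v <= 0) || any(h$q <= 0)) {
    stop("f, v and q must be strictly positive")
  }
  hm <- params$hemo
  fv <- h$v^(1 / hm$alpha)
  E <- 1 - (1 - hm$rho)^(1 / h$f)
  list(s = hm$epsilon * x - hm$kappa * h$s - hm$gamma * (h$f - 1),
       f = h$s,
       v = (h$f - fv) / hm$tau,
       q = (h$f * E / hm$rho - fv * h$q / h$v) / hm$tau)
}

as_hemo_state <- function(h, n) {
  if (is.matrix(h)) h <- list(s = h[, 1], f = h[, 2], v = h[, 3], q = h[, 4])
  stopifnot(all(c("s", "f", "v", "q") %in% names(h)),
            all(lengths(h[c("s", "f", "v", "q")]) == n))
  h
}

#' Resting haemodynamic state
#' @param n number of regions.
#' @return List with `s = 0`, `f = v = q = 1` per region.
#' @export
rest_state <- function(n) {
  list(s = numeric(n), f = rep(1, n), v = rep(1, n), q = rep(1, n))
}

#' BOLD readout
#'
#' Static non-linear readout of venous volume and deoxyhaemoglobin:
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` with `V0 = 0.04`,
#' `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`. The rest state maps to 0;
#' values are signal change relative to baseline (multiply by 100 for
#' percent).
#'
#' @param h haemodynamic state (see [hemodynamic_derivative()]).
#' @param params a `dcm_params` object.
#' @return Length-n BOLD signal vector.
#' @export
bold_observation <- function(h, params) {
  stopifnot(inherits(params, "dcm_params"))
  h <- as_hemo_state(h, params$spec$regions$n)
  if (any(h$v <= 0) || any(h$q <= 0)) stop("v and q must be strictly positive")
  rho <- params$hemo$rho
  params$V0 * (7 * rho * (1 - h$q) + 2 * (1 - h$q / h$v) +
               (2 * rho - 0.2) * (1 - h$v))
}

params_cpp_args <- function(params) {
  has_b <- any(vapply(params$b, function(x) any(x != 0), logical(1)))
  has_d <- any(vapply(params$d, function(x) any(x != 0), logical(1)))
  n <- params$spec$regions$n
  list(
    A = params$a,
    B = if (has_b) params$b[[1]] else NULL,
    C = as.numeric(params$c[, 1]),
    D = if (has_d) unlist(params$d) else NULL,
    hemo = params$hemo, V0 = params$V0
  )
}

#' Integrate a dynamic causal model
#'
#' Deterministically integrates the coupled neuronal and haemodynamic
#' equations from rest with a fixed-step fourth-order Runge-Kutta scheme at
#' the paradigm's micro-time step, and returns the fine-grid BOLD signal
#' together with the values sampled at the paradigm's acquisition reference
#' points.
#'
#' @param spec a `dcm_model_spec` (must match `params$spec`).
#' @param params a `dcm_params` object.
#' @param paradigm a `dcm_paradigm`.
#' @param return_fine keep the full fine-grid trajectory (default `TRUE`).
#' @return A list of class `dcm_simulation`: `time` (s), `bold`
#'   (n x timesteps fine-grid matrix), `samples` (n x n_scans matrix at
#'   acquisition reference points), `paradigm`.
#' @export
integrate_model <- function(spec, params, paradigm, return_fine = TRUE) {
  stopifnot(inherits(params, "dcm_params"), inherits(paradigm, "dcm_paradigm"))
  if (!missing(spec) && !is.null(spec) && !identical(spec$name, params$spec$name)) {
    stopifnot(identical(spec$a_support, params$spec$a_support))
  }
  spec <- params$spec
  st <- paradigm$sample_times
  if (is.unsorted(st)) stop("acquisition sample times must be sorted")
  if (any(st < 0) || any(st > paradigm$duration)) {
    stop("acquisition times outside the simulated span")
  }
  a <- params_cpp_args(params)
  res <- integrate_dcm_cpp(a$A, a$B, a$C, a$D,
                           a$hemo$kappa, a$hemo$gamma, a$hemo$tau,
                           a$hemo$alpha, a$hemo$rho, a$hemo$epsilon, a$V0,
                           paradigm$stim_onsets, paradigm$stim_durations,
                           paradigm$dt, paradigm$duration, st, return_fine)
  if (isTRUE(res$diverged)) {
    stop("integration diverged for model '", spec$name,
         "' (unstable parameters)")
  }
  rownames(res$samples) <- spec$regions$labels
  out <- list(samples = res$samples, paradigm = paradigm)
  if (return_fine) {
    rownames(res$fine) <- spec$regions$labels
    out$time <- res$time
    out$bold <- res$fine
  }
  structure(out, class = "dcm_simulation")
}

#' Sample a fine-grid BOLD trajectory at acquisition times
#'
#' Takes one sample per acquisition per region at the paradigm's reference
#' point inside each acquisition window (linear interpolation on the fine
#' grid).
#'
#' @param bold n x timesteps fine-grid matrix.
#' @param paradigm a `dcm_paradigm`.
#' @param time time vector matching `ncol(bold)`; defaults to the
#'   integration grid.
#' @return n x n_scans matrix.
#' @export
sample_acquisitions <- function(bold, paradigm,
                                time = seq(0, by = paradigm$dt, length.out = ncol(bold))) {
  stopifnot(is.matrix(bold), length(time) == ncol(bold))
  st <- paradigm$sample_times
  if (any(st < min(time)) || any(st > max(time) + 1e-9)) {
    stop("acquisition times outside the simulated span")
  }
  out <- t(vapply(seq_len(nrow(bold)), function(i) {
    stats::approx(time, bold[i, ], xout = pmin(st, max(time)), rule = 2)$y
  }, numeric(length(st))))
  rownames(out) <- rownames(bold)
  out
}

#' Predicted BOLD at acquisition times only
#'
#' Fast path used by the model inversion: integrates without storing the
#' fine grid.
#'
#' @inheritParams integrate_model
#' @return n x n_scans matrix, or `NULL` if the integration diverged (the
#'   caller decides how to handle instability).
#' @export
predict_bold <- function(params, paradigm) {
  a <- params_cpp_args(params)
  res <- integrate_dcm_cpp(a$A, a$B, a$C, a$D,
                           a$hemo$kappa, a$hemo$gamma, a$hemo$tau,
                           a$hemo$alpha, a$hemo$rho, a$hemo$epsilon, a$V0,
                           paradigm$stim_onsets, paradigm$stim_durations,
                           paradigm$dt, paradigm$duration,
                           paradigm$sample_times, FALSE)
  if (isTRUE(res$diverged)) return(NULL)
  rownames(res$samples) <- params$spec$regions$labels
  res$samples
}

#' Export a BOLD matrix as delimited text
#'
#' Writes a tab-separated table with a time column (seconds) and one column
#' per region.
#'
#' @param bold n x timesteps matrix with region rownames.
#' @param time time vector (s).
#' @param path file path.
#' @export
write_bold_table <- function(bold, time, path) {
  df <- data.frame(time = time, t(bold), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_table
#' @return `read_bold_table` returns a list with `time` and the n x scans
#'   `bold` matrix.
#' @export
read_bold_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  bold <- t(as.matrix(df[, -1, drop = FALSE]))
  list(time = df$time, bold = bold)
}
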