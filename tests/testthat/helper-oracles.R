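# Independent oracles used across the test files. Each reimplements the
# quantity under test from first principles, sharing as little code as
# possible with the package internals.

# ---------------------------------------------------------------------------
# Reference integrator: a pure-R fixed-step RK4 over the full coupled system,
# built from the package's R-level derivative functions (which are themselves
# tested term by term against loops below). Mirrors the sampling convention
# (linear interpolation at acquisition reference points).
r_integrate_oracle <- function(params, paradigm) {
  n <- params$spec$regions$n
  dt <- paradigm$dt
  nsteps <- ceiling(paradigm$duration / dt - 1e-9)
  u_of <- function(t) {
    on <- paradigm$stim_onsets
    dur <- paradigm$stim_durations
    as.numeric(any(t >= on & t < on + dur))
  }
  state <- c(numeric(n), numeric(n), rep(1, n), rep(1, n), rep(1, n))
  deriv <- function(y, u) {
    x <- y[1:n]
    h <- list(s = y[n + 1:n], f = y[2 * n + 1:n],
              v = y[3 * n + 1:n], q = y[4 * n + 1:n])
    dx <- neuronal_derivative(x, u, params)
    dh <- hemodynamic_derivative(h, x, params)
    c(dx, dh$s, dh$f, dh$v, dh$q)
  }
  bold_of <- function(y) {
    bold_observation(list(s = y[n + 1:n], f = y[2 * n + 1:n],
                          v = y[3 * n + 1:n], q = y[4 * n + 1:n]), params)
  }
  time <- (0:nsteps) * dt
  xs <- matrix(0, n, nsteps + 1)
  bold <- matrix(0, n, nsteps + 1)
  bold[, 1] <- bold_of(state)
  for (s in seq_len(nsteps)) {
    t <- (s - 1) * dt
    k1 <- deriv(state, u_of(t))
    k2 <- deriv(state + dt / 2 * k1, u_of(t + dt / 2))
    k3 <- deriv(state + dt / 2 * k2, u_of(t + dt / 2))
    k4 <- deriv(state + dt * k3, u_of(t + dt))
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    xs[, s + 1] <- state[1:n]
    bold[, s + 1] <- bold_of(state)
  }
  samples <- t(vapply(seq_len(n), function(i) {
    stats::approx(time, bold[i, ], xout = paradigm$sample_times, rule = 2)$y
  }, numeric(length(paradigm$sample_times))))
  list(time = time, x = xs, bold = bold, samples = samples)
}

# ---------------------------------------------------------------------------
# Matrix-exponential closed form for the linear neuronal subsystem under a
# constant input u: x(t) = (expm(A t) - I) A^{-1} C u from rest.
expm_linear_x <- function(A, Cu, times) {
  n <- nrow(A)
  Ainv_Cu <- solve(A, Cu)
  vapply(times, function(t) {
    E <- as.matrix(Matrix::expm(A * t))
    as.numeric((E - diag(n)) %*% Ainv_Cu)
  }, numeric(n))
}

# ---------------------------------------------------------------------------
# Grid integration of the K = 2 hierarchical random-effects model:
# r ~ Beta(alpha0, alpha0); model of subject n ~ Categorical(r, 1 - r);
# F[n, k] are the subject log evidences. Returns the exact posterior mean of
# (r, 1 - r) and the exact P(r > 1/2) / P(r < 1/2).
grid_bms_oracle <- function(F, alpha0 = 1, n_grid = 20001) {
  stopifnot(ncol(F) == 2)
  r <- seq(1e-8, 1 - 1e-8, length.out = n_grid)
  log_lik <- rep(0, n_grid)
  for (nn in seq_len(nrow(F))) {
    m <- max(F[nn, ])
    l1 <- exp(F[nn, 1] - m); l2 <- exp(F[nn, 2] - m)
    log_lik <- log_lik + log(r * l1 + (1 - r) * l2) + m
  }
  log_post <- (alpha0 - 1) * log(r) + (alpha0 - 1) * log(1 - r) + log_lik
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  er1 <- sum(w * r)
  phi1 <- sum(w[r > 0.5])
  list(expected_r = c(er1, 1 - er1), phi = c(phi1, 1 - phi1))
}

# ---------------------------------------------------------------------------
# Rebuild a dcm_params object from a fit's named posterior mean using only
# exported constructors (self-connections are -0.5 exp(theta_self); the
# efficacies enter through the haemodynamic constants).
params_from_theta <- function(theta, spec) {
  n <- spec$regions$n
  lab <- spec$regions$labels
  a <- matrix(0, n, n, dimnames = list(lab, lab))
  b <- lapply(spec$b_supports, function(s) s * 0)
  cmat <- matrix(0, n, ncol(spec$c_support))
  d <- lapply(spec$d_supports, function(s) s * 0)
  eps <- rep(1, n)
  for (nm in names(theta)) {
    val <- theta[[nm]]
    if (grepl("^a:", nm)) {
      st <- strsplit(sub("^a:", "", nm), "->", fixed = TRUE)[[1]]
      a[st[2], st[1]] <- val
    } else if (grepl("^self:", nm)) {
      reg <- sub("^self:", "", nm)
      a[reg, reg] <- -0.5 * exp(val)
    } else if (grepl("^b:", nm)) {
      st <- strsplit(sub("^b:", "", nm), "->", fixed = TRUE)[[1]]
      b[[1]][match(st[2], lab), match(st[1], lab)] <- val
    } else if (grepl("^c:", nm)) {
      cmat[match(sub("^c:", "", nm), lab), 1] <- val
    } else if (grepl("^d:", nm)) {
      st <- strsplit(sub("^d:", "", nm), "~", fixed = TRUE)[[1]]
      gater <- st[1]
      con <- strsplit(st[2], "->", fixed = TRUE)[[1]]
      d[[match(gater, lab)]][match(con[2], lab), match(con[1], lab)] <- val
    } else if (grepl("^eps:", nm)) {
      eps[match(sub("^eps:", "", nm), lab)] <- val
    } else stop("unknown parameter name: ", nm)
  }
  model_parameters(spec, a = a, b = b, c = cmat, d = d,
                   hemo = default_hemo(n, epsilon = eps))
}

# Independent recomputation of the variational free energy of a fit:
# accuracy with the expected sum of squares (residual SSR + Jacobian trace
# term, Jacobian rebuilt by forward finite differences through the public
# prediction API) minus the two Gaussian KL complexity terms.
free_energy_oracle <- function(fit, data, fd_step = 1e-3) {
  spec <- fit$spec
  n <- spec$regions$n
  Tn <- ncol(data$bold)
  theta <- fit$mean
  p <- length(theta)
  g0 <- predict_bold(params_from_theta(theta, spec), data$paradigm)
  J <- matrix(0, n * Tn, p)
  for (k in seq_len(p)) {
    th <- theta
    th[k] <- th[k] + fd_step
    gk <- predict_bold(params_from_theta(th, spec), data$paradigm)
    J[, k] <- (as.vector(gk) - as.vector(g0)) / fd_step
  }
  region_idx <- rep(seq_len(n), times = Tn)
  evec <- as.vector(data$bold) - as.vector(g0)
  ssr <- as.vector(rowsum(evec^2, region_idx))
  trr <- as.vector(rowsum(rowSums((J %*% fit$cov) * J), region_idx))
  P <- exp(fit$lambda)
  acc <- sum(Tn / 2 * fit$lambda - P / 2 * (ssr + trr)) -
    n * Tn / 2 * log(2 * pi)
  pv <- fit$priors$theta$var
  pm <- fit$priors$theta$mean
  dmu <- unname(theta) - pm
  kl_theta <- 0.5 * (sum(diag(fit$cov) / pv) + sum(dmu^2 / pv) - p +
                       sum(log(pv)) - determinant(fit$cov)$modulus[1])
  l0 <- fit$priors$lambda$mean
  lv0 <- fit$priors$lambda$var
  kl_lambda <- 0.5 * sum((fit$lambda - l0)^2 / lv0 + fit$lambda_var / lv0 -
                           1 + log(lv0 / fit$lambda_var))
  acc - kl_theta - kl_lambda
}

# Term-by-term loop evaluation of the neuronal state equation.
neuronal_deriv_loops <- function(x, u, params) {
  n <- length(x)
  dx <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      aij <- params$a[i, j]
      for (k in seq_along(u)) aij <- aij + u[k] * params$b[[k]][i, j]
      for (k in seq_len(n)) aij <- aij + x[k] * params$d[[k]][i, j]
      dx[i] <- dx[i] + aij * x[j]
    }
    for (k in seq_along(u)) dx[i] <- dx[i] + params$c[i, k] * u[k]
  }
  dx
}

# Small shared fixtures --------------------------------------------------

# A fast test paradigm/cohort size used where the full study conditions are
# not the point of the assertion (documented package test-problem size).
fast_cohort <- function(seed, spec = build_pruned_winner(),
                        params = auditory_ground_truth(spec),
                        n_subjects = 10, ...) {
  simulate_cohort(cohort_spec(spec = spec, params = params,
                              n_subjects = n_subjects, n_scans = 32,
                              dt = 0.5, seed = seed, ...))
}
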