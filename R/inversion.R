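#' Per-subject BOLD data
#'
#' @param id subject identifier.
#' @param bold region x scan numeric matrix (rownames must match the region
#'   labels of any spec it is fitted with); no missing values.
#' @param paradigm the `dcm_paradigm` under which `bold` was acquired.
#' @return An object of class `dcm_subject`.
#' @export
subject_data <- function(id, bold, paradigm) {
  stopifnot(is.matrix(bold), inherits(paradigm, "dcm_paradigm"))
  if (anyNA(bold) || any(!is.finite(bold))) stop("bold contains missing or non-finite values")
  if (ncol(bold) != length(paradigm$sample_times)) {
    stop("bold has ", ncol(bold), " scans but the paradigm defines ",
         length(paradigm$sample_times))
  }
  structure(list(id = as.character(id), bold = bold, paradigm = paradigm),
            class = "dcm_subject")
}

#' @export
print.dcm_subject <- function(x, ...) {
  cat(sprintf("<dcm_subject> %s: %d regions x %d scans\n",
              x$id, nrow(x$bold), ncol(x$bold)))
  invisible(x)
}

# Free-parameter bookkeeping: maps the flat parameter vector onto the
# supported entries of a, the self-connection log-scalings, b, c, d and the
# per-region signal efficacies.
build_param_map <- function(spec) {
  n <- spec$regions$n
  lab <- spec$regions$labels
  blocks <- list()
  off <- which(spec$a_support == 1 & row(spec$a_support) != col(spec$a_support))
  blocks$a <- list(idx = off,
                   names = sprintf("a:%s->%s", lab[(off - 1) %/% n + 1],
                                   lab[(off - 1) %% n + 1]))
  blocks$self <- list(idx = which(diag(n) == 1),
                      names = sprintf("self:%s", lab))
  m <- ncol(spec$c_support)
  b_idx <- lapply(seq_len(m), function(k) which(spec$b_supports[[k]] == 1))
  blocks$b <- list(idx = b_idx[[1]],
                   names = if (length(b_idx[[1]]))
                     sprintf("b:%s->%s", lab[(b_idx[[1]] - 1) %/% n + 1],
                             lab[(b_idx[[1]] - 1) %% n + 1]) else character(0))
  c_idx <- which(spec$c_support == 1)
  blocks$c <- list(idx = c_idx, names = sprintf("c:%s", lab[(c_idx - 1) %% n + 1]))
  d_idx <- lapply(seq_len(n), function(j) which(spec$d_supports[[j]] == 1))
  d_names <- unlist(lapply(seq_len(n), function(j) {
    ii <- d_idx[[j]]
    if (!length(ii)) return(character(0))
    sprintf("d:%s~%s->%s", lab[j], lab[(ii - 1) %/% n + 1], lab[(ii - 1) %% n + 1])
  }))
  blocks$d <- list(idx = d_idx, names = d_names)
  blocks$eps <- list(idx = seq_len(n), names = sprintf("eps:%s", lab))
  sizes <- c(a = length(blocks$a$idx), self = n, b = length(blocks$b$idx),
             c = length(blocks$c$idx), d = sum(lengths(d_idx)), eps = n)
  starts <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(starts) <- names(sizes)
  list(spec = spec, n = n, blocks = blocks, sizes = sizes, starts = starts,
       p = sum(sizes),
       names = c(blocks$a$names, blocks$self$names, blocks$b$names,
                 blocks$c$names, blocks$d$names, blocks$eps$names))
}

# theta -> dcm parameter matrices (no validation; used inside the inverter,
# where instability is handled by step rejection)
theta_to_matrices <- function(map, theta, hemo) {
  n <- map$n
  sl <- function(block) {
    k <- map$sizes[block]
    if (k == 0) return(numeric(0))
    theta[(map$starts[block] + 1):(map$starts[block] + k)]
  }
  A <- matrix(0, n, n)
  A[map$blocks$a$idx] <- sl("a")
  diag(A) <- -0.5 * exp(sl("self"))
  B <- NULL
  if (map$sizes["b"] > 0) {
    B <- matrix(0, n, n)
    B[map$blocks$b$idx] <- sl("b")
  }
  Cv <- numeric(n)
  Cv[(map$blocks$c$idx - 1) %% n + 1] <- sl("c")
  D <- NULL
  if (map$sizes["d"] > 0) {
    D <- numeric(n * n * n)
    dv <- sl("d")
    pos <- 0
    for (j in seq_len(n)) {
      ii <- map$blocks$d$idx[[j]]
      if (length(ii)) {
        D[(j - 1) * n * n + ii] <- dv[pos + seq_along(ii)]
        pos <- pos + length(ii)
      }
    }
  }
  hemo$epsilon <- sl("eps")
  list(A = A, B = B, C = Cv, D = D, hemo = hemo)
}

predict_theta <- function(map, theta, hemo, paradigm) {
  mm <- theta_to_matrices(map, theta, hemo)
  res <- integrate_dcm_cpp(mm$A, mm$B, mm$C, mm$D,
                           mm$hemo$kappa, mm$hemo$gamma, mm$hemo$tau,
                           mm$hemo$alpha, mm$hemo$rho, mm$hemo$epsilon, 0.04,
                           paradigm$stim_onsets, paradigm$stim_durations,
                           paradigm$dt, paradigm$duration,
                           paradigm$sample_times, FALSE)
  if (isTRUE(res$diverged)) NULL else res$samples
}

#' Default priors for a model specification
#'
#' Shrinkage priors over the free parameters: couplings N(0, 0.0625 Hz^2)
#' (prior sd 0.25 Hz, half the fixed self-decay scale - with a sparse
#' design the between-region couplings are only partially identified, and
#' this shrinkage scale pins the unidentified directions at the
#' minimum-norm solution without biasing couplings of the typical 0.1-0.3
#' Hz magnitude); modulations and gating strengths N(0, 0.25); driving
#' inputs N(0, 1); self-connection log-scalings N(0, 0.0625) (the
#' self-connection is `-0.5 exp(theta)`, negative by construction); signal
#' efficacy N(1, 0.0625) per region; and an observation-noise
#' log-precision prior N(0, 1) per region.
#'
#' @param spec a `dcm_model_spec`.
#' @return A list of class `dcm_priors` with a data frame `theta`
#'   (name/mean/var per free parameter) and `lambda` (mean/var of the noise
#'   log-precision).
#' @export
default_priors <- function(spec) {
  map <- build_param_map(spec)
  mean <- numeric(map$p)
  var <- numeric(map$p)
  fill <- function(block, m, v) {
    k <- map$sizes[block]
    if (k > 0) {
      at <- (map$starts[block] + 1):(map$starts[block] + k)
      mean[at] <<- m; var[at] <<- v
    }
  }
  fill("a", 0, 0.0625); fill("self", 0, 0.0625); fill("b", 0, 0.25)
  fill("c", 0, 1); fill("d", 0, 0.25); fill("eps", 1, 0.0625)
  structure(list(theta = data.frame(name = map$names, mean = mean, var = var,
                                    stringsAsFactors = FALSE),
                 lambda = list(mean = 0, var = 1)),
            class = "dcm_priors")
}

#' Inversion settings
#'
#' @param max_iter maximum Gauss-Newton iterations (default 64).
#' @param tol convergence tolerance on the free-energy change (nats,
#'   default 0.01).
#' @param fd_step finite-difference step for the response Jacobian.
#' @param max_halvings maximum step halvings in the line search.
#' @return A list of settings.
#' @export
fit_settings <- function(max_iter = 64, tol = 0.01, fd_step = 1e-3,
                         max_halvings = 8) {
  list(max_iter = max_iter, tol = tol, fd_step = fd_step,
       max_halvings = max_halvings)
}

#' Invert a dynamic causal model for one subject
#'
#' Variational-Laplace estimation of the posterior over the model's free
#' parameters: a Gaussian posterior is optimized by Gauss-Newton ascent on
#' the variational free energy (a lower bound on the log model evidence
#' balancing accuracy against complexity), with a step-halving line search
#' and per-region observation-noise precisions updated by Newton steps.
#' Unstable parameter proposals are handled by step rejection. On
#' non-convergence the best-found fit is returned with a warning flag.
#'
#' @param data a `dcm_subject`.
#' @param spec a `dcm_model_spec` whose regions match the data rows.
#' @param priors a `dcm_priors` object (default [default_priors()]).
#' @param settings see [fit_settings()].
#' @param hemo fixed haemodynamic constants (efficacy `epsilon` is
#'   estimated; the rest are held at these values).
#' @return An object of class `dcm_fit`: posterior `mean` (named vector),
#'   `cov`, free energy `F` (nats) with components `accuracy` and
#'   `complexity`, `fitted` response matrix, `residual_var` per region,
#'   noise log-precisions `lambda` (+ `lambda_var`), an `iterations` log,
#'   and `converged`/`warning` flags.
#' @export
fit_dcm <- function(data, spec, priors = default_priors(spec),
                    settings = fit_settings(),
                    hemo = default_hemo(spec$regions$n)) {
  stopifnot(inherits(data, "dcm_subject"), inherits(spec, "dcm_model_spec"))
  if (nrow(data$bold) != spec$regions$n) {
    stop("data has ", nrow(data$bold), " regions but spec has ", spec$regions$n)
  }
  if (!is.null(rownames(data$bold)) &&
      !identical(rownames(data$bold), spec$regions$labels)) {
    stop("data region labels do not match the model spec")
  }
  map <- build_param_map(spec)
  stopifnot(identical(priors$theta$name, map$names))
  y <- data$bold
  n <- nrow(y); Tn <- ncol(y)
  region_idx <- rep(seq_len(n), times = Tn)  # as.vector(y) stacks scans, region fastest
  yv <- as.vector(y)
  prior_mean <- priors$theta$mean
  prior_var <- priors$theta$var
  S0inv <- 1 / prior_var
  l0 <- priors$lambda$mean
  lv0 <- priors$lambda$var
  p <- map$p

  mu <- prior_mean
  g <- predict_theta(map, mu, hemo, data$paradigm)
  if (is.null(g)) stop("integration diverged at the prior mean for '", spec$name, "'")
  ev <- yv - as.vector(g)
  lambda <- rep(-log(max(mean(ev^2), 1e-8)), n)

  jacobian <- function(mu, g) {
    J <- matrix(0, n * Tn, p)
    h <- settings$fd_step
    for (k in seq_len(p)) {
      th <- mu; th[k] <- th[k] + h
      gk <- predict_theta(map, th, hemo, data$paradigm)
      if (is.null(gk)) {
        th[k] <- mu[k] - h
        gk <- predict_theta(map, th, hemo, data$paradigm)
        if (is.null(gk)) next
        J[, k] <- (as.vector(g) - as.vector(gk)) / h
      } else {
        J[, k] <- (as.vector(gk) - as.vector(g)) / h
      }
    }
    J
  }

  ssr_by_region <- function(evec) {
    as.vector(rowsum(evec^2, region_idx))
  }

  # posterior covariance given J and lambda
  post_cov <- function(J, lambda) {
    w <- exp(lambda)[region_idx]
    H <- crossprod(J * sqrt(w))
    H <- (H + t(H)) / 2
    Hp <- H + diag(S0inv, p)
    R <- chol(Hp)
    Sth <- chol2inv(R)
    list(Sth = Sth, logdet_Sth = -2 * sum(log(diag(R))), H = H)
  }

  trace_by_region <- function(J, Sth) {
    tr <- rowSums((J %*% Sth) * J)
    as.vector(rowsum(tr, region_idx))
  }

  free_energy_full <- function(mu, evec, lambda, Sth, logdet_Sth, trr) {
    ssr <- ssr_by_region(evec)
    Essr <- ssr + trr
    P <- exp(lambda)
    lambda_var <- 1 / (P / 2 * Essr + 1 / lv0)
    acc <- sum(Tn / 2 * lambda - P / 2 * Essr) - n * Tn / 2 * log(2 * pi)
    dmu <- mu - prior_mean
    kl_theta <- 0.5 * (sum(diag(Sth) * S0inv) + sum(dmu^2 * S0inv) - p +
                         sum(log(prior_var)) - logdet_Sth)
    kl_lambda <- 0.5 * sum((lambda - l0)^2 / lv0 + lambda_var / lv0 - 1 +
                             log(lv0 / lambda_var))
    list(F = acc - kl_theta - kl_lambda, accuracy = acc,
         complexity = kl_theta + kl_lambda, lambda_var = lambda_var)
  }

  iter_log <- data.frame(iter = integer(0), F = numeric(0), step = numeric(0))
  converged <- FALSE
  F_cur <- -Inf
  Sth <- diag(prior_var, p)
  logdet_Sth <- sum(log(prior_var))
  J <- NULL

  for (iter in seq_len(settings$max_iter)) {
    J <- jacobian(mu, g)
    evec <- yv - as.vector(g)
    # noise precision updates interleaved with the covariance
    for (rep in 1:3) {
      pc <- post_cov(J, lambda)
      trr <- trace_by_region(J, pc$Sth)
      Essr <- ssr_by_region(evec) + trr
      P <- exp(lambda)
      grad <- Tn / 2 - P / 2 * Essr - (lambda - l0) / lv0
      hess <- -P / 2 * Essr - 1 / lv0
      step <- pmax(pmin(-grad / hess, 2), -2)
      lambda <- lambda + step
    }
    pc <- post_cov(J, lambda)
    Sth <- pc$Sth; logdet_Sth <- pc$logdet_Sth
    trr <- trace_by_region(J, Sth)
    fe <- free_energy_full(mu, evec, lambda, Sth, logdet_Sth, trr)
    F_cur <- fe$F

    # Gauss-Newton direction on the free energy
    w <- exp(lambda)[region_idx]
    grad_mu <- crossprod(J, w * evec) - S0inv * (mu - prior_mean)
    dmu_full <- as.vector(Sth %*% grad_mu)

    accepted <- FALSE
    for (k in 0:settings$max_halvings) {
      mu_try <- mu + dmu_full / 2^k
      g_try <- predict_theta(map, mu_try, hemo, data$paradigm)
      if (is.null(g_try)) next
      fe_try <- free_energy_full(mu_try, yv - as.vector(g_try), lambda,
                                 Sth, logdet_Sth, trr)
      if (fe_try$F > F_cur) {
        dF <- fe_try$F - F_cur
        mu <- mu_try; g <- g_try; F_cur <- fe_try$F
        iter_log <- rbind(iter_log,
                          data.frame(iter = iter, F = F_cur, step = 1 / 2^k))
        accepted <- TRUE
        if (dF < settings$tol) converged <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }

  # final curvature, noise and free energy at the accepted optimum
  J <- jacobian(mu, g)
  evec <- yv - as.vector(g)
  for (rep in 1:3) {
    pc <- post_cov(J, lambda)
    trr <- trace_by_region(J, pc$Sth)
    Essr <- ssr_by_region(evec) + trr
    P <- exp(lambda)
    grad <- Tn / 2 - P / 2 * Essr - (lambda - l0) / lv0
    hess <- -P / 2 * Essr - 1 / lv0
    lambda <- lambda + pmax(pmin(-grad / hess, 2), -2)
  }
  pc <- post_cov(J, lambda)
  trr <- trace_by_region(J, pc$Sth)
  fe <- free_energy_full(mu, evec, lambda, pc$Sth, pc$logdet_Sth, trr)

  names(mu) <- map$names
  dimnames(pc$Sth) <- list(map$names, map$names)
  resid <- matrix(evec, n, Tn)
  structure(list(
    mean = mu, cov = pc$Sth, F = fe$F,
    F_parts = c(accuracy = fe$accuracy, complexity = fe$complexity),
    fitted = g, residual_var = stats::setNames(1 / exp(lambda), spec$regions$labels),
    lambda = lambda, lambda_var = fe$lambda_var,
    iterations = iter_log, converged = converged,
    warning = !converged,
    subject = data$id, spec = spec, priors = priors, settings = settings,
    n_scans = Tn), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %s on subject %s: F = %.2f nats, %d iterations%s\n",
              x$spec$name, x$subject, x$F, nrow(x$iterations),
              if (x$warning) " (did not converge)" else ""))
  invisible(x)
}

#' Free energy of a fit
#'
#' The variational free energy approximates the log model evidence as an
#' accuracy term minus a complexity term (the KL divergence from the prior
#' to the posterior); it is the quantity compared across models in Bayesian
#' model selection.
#'
#' @param fit a `dcm_fit`.
#' @return Scalar free energy in nats.
#' @export
free_energy <- function(fit) {
  stopifnot(inherits(fit, "dcm_fit"))
  fit$F
}

#' Posterior probability that a connection exceeds a threshold
#'
#' One-sided posterior mass `P(theta > threshold)` under the Gaussian
#' marginal posterior of a coupling parameter.
#'
#' @param fit a `dcm_fit`.
#' @param connection either a parameter name (e.g. `"a:LSTG->LHG"`,
#'   `"c:RSTG"`) or a length-2 vector `c(source, target)` denoting the
#'   coupling source -> target.
#' @param threshold coupling threshold in Hz (default 0).
#' @return Probability in \[0, 1\].
#' @export
connection_posterior_prob <- function(fit, connection, threshold = 0) {
  stopifnot(inherits(fit, "dcm_fit"))
  nm <- if (length(connection) == 2) {
    sprintf("a:%s->%s", connection[1], connection[2])
  } else as.character(connection)
  if (!nm %in% names(fit$mean)) stop("unknown connection: ", nm)
  m <- fit$mean[[nm]]
  s <- sqrt(fit$cov[nm, nm])
  if (s == 0) return(as.numeric(m > threshold))
  stats::pnorm(threshold, mean = m, sd = s, lower.tail = FALSE)
}

#' Serialize a fit report
#'
#' Writes a structured-text (YAML) report with the parameter table
#' (posterior mean, sd, one-sided `P(theta > 0)`), free energy and settings,
#' and, alongside it, a delimited-text fitted-vs-observed table when the
#' observed data are supplied.
#'
#' @param fit a `dcm_fit`.
#' @param path output file path (YAML report).
#' @param data optional `dcm_subject`; when given, a
#'   `<path>_fitted.tsv` table of observed and fitted values is written.
#' @export
write_fit_report <- function(fit, path, data = NULL) {
  sd <- sqrt(diag(fit$cov))
  P <- stats::pnorm(0, fit$mean, ifelse(sd > 0, sd, Inf), lower.tail = FALSE)
  doc <- list(model = fit$spec$name, subject = fit$subject,
              free_energy = fit$F,
              accuracy = unname(fit$F_parts["accuracy"]),
              complexity = unname(fit$F_parts["complexity"]),
              converged = fit$converged,
              settings = fit$settings,
              parameters = lapply(seq_along(fit$mean), function(i) {
                list(name = names(fit$mean)[i], mean = unname(fit$mean[i]),
                     sd = unname(sd[i]), P = unname(P[i]))
              }))
  yaml::write_yaml(doc, path)
  if (!is.null(data)) {
    tab <- data.frame(time = data$paradigm$sample_times,
                      region = rep(rownames(data$bold), each = ncol(data$bold)),
                      observed = as.vector(t(data$bold)),
                      fitted = as.vector(t(fit$fitted)))
    utils::write.table(tab, paste0(path, "_fitted.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
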