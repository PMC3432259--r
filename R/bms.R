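#' Log-evidence table
#'
#' Container for the subject-by-model free energies (log-evidence
#' approximations, nats) entering group model selection.
#'
#' @param F N x K numeric matrix (subjects by models), all finite.
#' @param subjects,models optional labels (defaults taken from dimnames).
#' @return An object of class `dcm_logev`.
#' @export
log_evidence_table <- function(F, subjects = rownames(F), models = colnames(F)) {
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop("log-evidences must be finite")
  if (nrow(F) < 1 || ncol(F) < 2) stop("need at least 1 subject and 2 models")
  if (is.null(subjects)) subjects <- paste0("sub", seq_len(nrow(F)))
  if (is.null(models)) models <- paste0("model", seq_len(ncol(F)))
  dimnames(F) <- list(subjects, models)
  structure(list(F = F, subjects = subjects, models = models,
                 N = nrow(F), K = ncol(F)), class = "dcm_logev")
}

#' Read and write log-evidence tables
#' @param table a `dcm_logev`.
#' @param path file path (tab-separated, subjects in rows, models in
#'   columns, headered, first column `subject`).
#' @export
write_log_evidence <- function(table, path) {
  df <- data.frame(subject = table$subjects, table$F, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_log_evidence
#' @export
read_log_evidence <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  F <- as.matrix(df[, -1, drop = FALSE])
  rownames(F) <- df$subject
  log_evidence_table(F)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies `r` follow a Dirichlet distribution whose parameters are
#' estimated from the subject-wise log evidences by a variational update.
#' Iterates `u_nk` proportional to `exp(F_nk + psi(alpha_k) - psi(sum
#' alpha))` (normalized within subject) and `alpha_k = alpha0_k + sum_n
#' u_nk` to a fixed point.
#'
#' The Dirichlet parameters `alpha` act as effective subject counts per
#' model (`sum(alpha) = sum(alpha0) + N`); the expected posterior model
#' probability is `<r> = alpha / sum(alpha)`; the exceedance probability
#' `phi_k` is the posterior probability that model `k` is the most frequent
#' in the population.
#'
#' @param table a `dcm_logev` (or bare N x K matrix).
#' @param alpha0 Dirichlet prior counts (scalar or length K, default 1 per
#'   model).
#' @param exceedance_method `"auto"` (analytic for K = 2, Monte Carlo
#'   otherwise), `"analytic"`, or `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count (default 1e6).
#' @param seed seed for the Monte-Carlo draw (default 1).
#' @param tol convergence tolerance on `max |delta alpha|`.
#' @param max_iter maximum update sweeps.
#' @return An object of class `dcm_bms`: `alpha`, `expected_r`, `phi`,
#'   `alpha0`, `u` (subject-wise model assignment probabilities), `N`, `K`.
#' @export
rfx_bms <- function(table, alpha0 = 1, exceedance_method = "auto",
                    n_samples = 1e6, seed = 1L, tol = 1e-6, max_iter = 1e4) {
  if (!inherits(table, "dcm_logev")) table <- log_evidence_table(table)
  F <- table$F
  N <- nrow(F); K <- ncol(F)
  alpha0 <- rep_len(as.numeric(alpha0), K)
  if (any(alpha0 <= 0)) stop("alpha0 must be positive")
  alpha <- alpha0 + N / K
  for (it in seq_len(max_iter)) {
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    u <- exp(lg)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  phi <- exceedance_prob(alpha, method = exceedance_method,
                         n_samples = n_samples, seed = seed)
  structure(list(alpha = stats::setNames(alpha, colnames(F)),
                 expected_r = stats::setNames(alpha / sum(alpha), colnames(F)),
                 phi = stats::setNames(phi, colnames(F)),
                 alpha0 = alpha0, u = u, N = N, K = K,
                 models = colnames(F)),
            class = "dcm_bms")
}

#' @export
print.dcm_bms <- function(x, digits = 4, ...) {
  cat(sprintf("<dcm_bms> %d subjects, %d models\n", x$N, x$K))
  tab <- rbind(alpha = x$alpha, `<r>` = x$expected_r, phi = x$phi)
  print(round(tab, digits))
  invisible(x)
}

#' Expected posterior model probabilities
#'
#' @param alpha positive Dirichlet parameters.
#' @return `alpha / sum(alpha)`.
#' @export
expected_posterior <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  alpha / sum(alpha)
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' `phi_k = P(r_k > r_j for all j != k)` with `r ~ Dirichlet(alpha)`: the
#' probability that model `k` is more frequent in the population than every
#' competitor. For K = 2 this is available in closed form through the
#' regularized incomplete beta function, `phi_2 = P(r_2 > 1/2) = 1 -
#' I_0.5(alpha_2, alpha_1)`; for K > 2 it is estimated by seeded Monte-Carlo
#' sampling.
#'
#' @param alpha positive Dirichlet parameters.
#' @param method `"auto"`, `"analytic"` (K = 2 only) or `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return Vector of K probabilities (sums to 1; Monte-Carlo up to sampling
#'   error).
#' @export
exceedance_prob <- function(alpha, method = c("auto", "analytic", "montecarlo"),
                            n_samples = 1e6, seed = 1L) {
  method <- match.arg(method)
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  K <- length(alpha)
  if (method == "auto") method <- if (K == 2) "analytic" else "montecarlo"
  if (method == "analytic") {
    if (K != 2) stop("analytic exceedance is only available for K = 2")
    p2 <- stats::pbeta(0.5, alpha[2], alpha[1], lower.tail = FALSE)
    return(c(1 - p2, p2))
  }
  phi <- numeric(K)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  withr_seed({
    block <- 1e5
    done <- 0
    counts <- numeric(K)
    while (done < n_samples) {
      nb <- min(block, n_samples - done)
      g <- matrix(stats::rgamma(nb * K, shape = rep(alpha, each = nb)), nb, K)
      counts <- counts + tabulate(max.col(g), nbins = K)
      done <- done + nb
    }
    phi <- counts / n_samples
  })
  phi
}

#' Serialize a BMS result
#'
#' Writes the three-row report (Dirichlet parameters, expected posterior
#' probabilities, exceedance probabilities) as a structured-text document.
#'
#' @param bms a `dcm_bms`.
#' @param path file path.
#' @export
write_bms_report <- function(bms, path) {
  doc <- list(models = as.list(if (is.null(bms$models)) paste0("model", seq_len(bms$K)) else bms$models),
              alpha = as.list(unname(bms$alpha)),
              expected_r = as.list(unname(bms$expected_r)),
              phi = as.list(unname(bms$phi)),
              alpha0 = as.list(bms$alpha0),
              N = bms$N, K = bms$K)
  yaml::write_yaml(doc, path)
  invisible(path)
}
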