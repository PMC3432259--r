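#' Default haemodynamic constants
#'
#' Per-region constants of the single-compartment balloon-Windkessel model:
#' vasodilatory signal decay `kappa` (1/s), flow feedback `gamma` (1/s),
#' mean transit time `tau` (s), vessel stiffness exponent `alpha` (unitless,
#' in (0,1)), resting oxygen extraction fraction `rho` (in (0,1)), and
#' neurovascular signal efficacy `epsilon` (unitless gain on neuronal
#' activity). The BOLD readout uses blood volume fraction `V0 = 0.04` with
#' coefficients `k1 = 7 rho`, `k2 = 2`, `k3 = 2 rho - 0.2`.
#'
#' @param n number of regions.
#' @param kappa,gamma,tau,alpha,rho,epsilon scalars or length-`n` vectors.
#' @return A list of length-`n` numeric vectors, one per constant.
#' @export
default_hemo <- function(n, kappa = 0.64, gamma = 0.32, tau = 2.0,
                         alpha = 0.32, rho = 0.4, epsilon = 1.0) {
  h <- list(kappa = kappa, gamma = gamma, tau = tau,
            alpha = alpha, rho = rho, epsilon = epsilon)
  h <- lapply(h, function(x) rep_len(as.numeric(x), n))
  if (any(unlist(h) <= 0)) stop("haemodynamic constants must be strictly positive")
  if (any(h$alpha >= 1) || any(h$rho >= 1)) stop("alpha and rho must lie in (0, 1)")
  h
}

#' Numeric model parameters
#'
#' Couples a [model_spec()] with numeric values: coupling matrix `a` (Hz;
#' off-diagonal entries only where the spec allows them, negative diagonal
#' self-connections), input modulations `b` (Hz per unit input), driving
#' inputs `c` (Hz per unit input), gating strengths `d` (Hz per unit
#' neuronal activity), and per-region haemodynamic constants.
#'
#' Entries must be zero wherever the owning spec's support is zero, and the
#' coupling matrix `a` must be dynamically stable (all eigenvalues with
#' negative real part). Self-connections default to -0.5 Hz.
#'
#' @param spec a `dcm_model_spec`.
#' @param a n x n coupling matrix (Hz). Missing diagonal entries are set to
#'   -0.5.
#' @param b list of m n x n matrices; defaults to zero.
#' @param c n x m driving-input matrix; defaults to zero.
#' @param d list of n n x n gating matrices; defaults to zero.
#' @param hemo haemodynamic constants, see [default_hemo()].
#' @return An object of class `dcm_params`.
#' @export
model_parameters <- function(spec, a = NULL, b = NULL, c = NULL, d = NULL,
                             hemo = default_hemo(spec$regions$n)) {
  stopifnot(inherits(spec, "dcm_model_spec"))
  n <- spec$regions$n
  m <- ncol(spec$c_support)
  lab <- spec$regions$labels
  if (is.null(a)) a <- matrix(0, n, n)
  a <- as.matrix(a) * 1.0
  if (all(diag(a) == 0)) diag(a) <- -0.5
  if (is.null(b)) b <- rep(list(matrix(0, n, n)), m)
  if (is.null(c)) c <- matrix(0, n, m)
  if (is.null(d)) d <- rep(list(matrix(0, n, n)), n)
  c <- matrix(as.numeric(c), n, m)
  dimnames(a) <- list(lab, lab)
  rownames(c) <- lab
  p <- structure(list(spec = spec, a = a, b = b, c = c, d = d, hemo = hemo,
                      V0 = 0.04),
                 class = "dcm_params")
  err <- validate_parameters(p)
  if (length(err)) stop("invalid parameters: ", paste(err, collapse = "; "))
  p
}

validate_parameters <- function(p) {
  err <- character(0)
  spec <- p$spec
  n <- spec$regions$n
  off <- row(spec$a_support) != col(spec$a_support)
  if (any(p$a[off] != 0 & spec$a_support[off] == 0)) {
    err <- c(err, "a has non-zero entries outside a_support")
  }
  if (any(diag(p$a) >= 0)) err <- c(err, "self-connections (diagonal of a) must be negative")
  for (k in seq_along(p$b)) {
    if (any(p$b[[k]] != 0 & spec$b_supports[[k]] == 0)) {
      err <- c(err, sprintf("b[[%d]] has entries outside its support", k))
    }
  }
  if (any(p$c != 0 & spec$c_support == 0)) err <- c(err, "c has entries outside c_support")
  for (k in seq_along(p$d)) {
    if (any(p$d[[k]] != 0 & spec$d_supports[[k]] == 0)) {
      err <- c(err, sprintf("d[[%d]] has entries outside its support", k))
    }
  }
  ev <- eigen(p$a, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) err <- c(err, "coupling matrix a is unstable (eigenvalue with non-negative real part)")
  err
}

#' @export
print.dcm_params <- function(x, ...) {
  cat(sprintf("<dcm_params> for %s (%d regions)\n", x$spec$name, x$spec$regions$n))
  cat("a (Hz):\n"); print(round(x$a, 4))
  if (any(x$c != 0)) { cat("c (Hz):\n"); print(round(x$c, 4)) }
  invisible(x)
}
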