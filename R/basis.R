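#' Sinc interpolation basis
#'
#' The ideal profile is modelled as a finite linear combination of `L`
#' ideal (sinc) interpolation functions on the unit interval,
#' \deqn{f(x) = \sum_{k=0}^{L-1} c_k\,\mathrm{sinc}(x/\Delta - k),}
#' with node spacing \eqn{\Delta = 1/(L-1)} and the normalized sinc
#' \eqn{\mathrm{sinc}(t) = \sin(\pi t)/(\pi t)}, \eqn{\mathrm{sinc}(0)=1}.
#' At the nodes \eqn{x = k\Delta} the basis interpolates: \eqn{f(k\Delta) = c_k}.
#'
#' @param x numeric vector of evaluation points in \[0, 1\].
#' @param L basis size (number of coefficients), `L >= 2`.
#' @return `L x length(x)` matrix; entry `(k, p)` is
#'   \eqn{\mathrm{sinc}(x_p/\Delta - (k-1))}.
#' @seealso [sinc_basis_deriv()], [compensate()]
#' @examples
#' phi <- sinc_basis(seq(0, 1, length.out = 5), L = 5)
#' round(phi, 12)  # identity: evaluation points are the nodes
#' @export
sinc_basis <- function(x, L) {
  stopifnot(is.numeric(x), L >= 2, L == round(L))
  delta <- 1 / (L - 1)
  t <- outer(0:(L - 1), x / delta, function(k, u) u - k)
  nsinc(t)
}

#' Derivative of the sinc interpolation basis
#'
#' Analytic derivative of the normalized sinc basis of [sinc_basis()],
#' \eqn{\dot\varphi_k(x) = (1/\Delta)\,\mathrm{sinc}'(x/\Delta - k)}, with the
#' removable singularity \eqn{\mathrm{sinc}'(0) = 0}. Used for the
#' location-update step, where the energy gradient needs
#' \eqn{\dot f(x) = \sum_k c_k \dot\varphi_k(x)}.
#'
#' @inheritParams sinc_basis
#' @return `L x length(x)` matrix of derivative values.
#' @export
sinc_basis_deriv <- function(x, L) {
  stopifnot(is.numeric(x), L >= 2, L == round(L))
  delta <- 1 / (L - 1)
  t <- outer(0:(L - 1), x / delta, function(k, u) u - k)
  nsinc_deriv(t) / delta
}

# normalized sinc sin(pi t)/(pi t) with sinc(0) = 1
nsinc <- function(t) {
  out <- rep(1, length(t))
  nz <- abs(t) > .Machine$double.eps
  pt <- pi * t[nz]
  out[nz] <- sin(pt) / pt
  array(out, dim = dim(t) %||% length(t))
}

# d/dt sinc(t) = (pi t cos(pi t) - sin(pi t)) / (pi t^2); odd, so 0 at t = 0.
# Near 0 use the series -pi^2 t/3 + pi^4 t^3/30 to avoid cancellation.
nsinc_deriv <- function(t) {
  out <- numeric(length(t))
  small <- abs(t) < 1e-4
  ts <- t[small]
  out[small] <- -pi^2 * ts / 3 + pi^4 * ts^3 / 30
  tb <- t[!small]
  pt <- pi * tb
  out[!small] <- (pt * cos(pt) - sin(pt)) / (pi * tb^2)
  array(out, dim = dim(t) %||% length(t))
}

#' Evaluate an ideal profile from its sinc coefficients
#'
#' @param x numeric vector of locations in \[0, 1\].
#' @param c numeric coefficient vector of length `L`.
#' @return numeric vector `f(x)`.
#' @export
eval_profile <- function(x, c) {
  drop(crossprod(sinc_basis(x, length(c)), c))
}

# derivative of the ideal profile at x
eval_profile_deriv <- function(x, c) {
  drop(crossprod(sinc_basis_deriv(x, length(c)), c))
}

#' Symmetry-constraint matrix for internuclear profiles
#'
#' An internuclear profile reads the same from cell A to cell B as from B to
#' A, so its template coefficients are constrained to be palindromic,
#' `c = P %*% c_tilde` with `c_tilde` of length `L/2`. `P` stacks the
#' `L/2` identity on top of its row-reversal, so `c[k] == c[L-1-k]` holds by
#' construction and `crossprod(P) == 2 * diag(L/2)`.
#'
#' @param L basis size; must be even.
#' @return `L x (L/2)` constraint matrix.
#' @export
symmetry_matrix <- function(L) {
  if (L %% 2 != 0) stop("symmetry constraint requires an even basis size L")
  half <- diag(L / 2)
  rbind(half, half[(L / 2):1, , drop = FALSE])
}

#' First-difference smoothness penalty
#'
#' Quadratic penalty matrix `psi` such that
#' `t(c) %*% psi %*% c == sum(diff(c)^2)`, i.e. `psi = t(D) %*% D` with `D`
#' the first-difference operator. Symmetric positive semidefinite with the
#' constant vector as null space; used both to smooth the template
#' coefficients (weight `alpha`) and as the tension prior on the location
#' columns (weight `beta`).
#'
#' @param n size of the penalized vector, `n >= 2`.
#' @return `n x n` penalty matrix.
#' @export
difference_penalty <- function(n) {
  stopifnot(n >= 2, n == round(n))
  D <- diff(diag(n))
  crossprod(D)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
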