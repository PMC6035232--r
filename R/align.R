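#' Observation weights for the alignment energy
#'
#' Diagonal weights \eqn{\sigma_{i,j} = \omega_j \gamma_{i,j}} of the weighted
#' least-squares form of the data-fidelity term. Under additive white
#' Gaussian noise (AWGN) \eqn{\gamma = 1}; under the Poisson model
#' \eqn{\gamma_{i,j} = 1 / (2 f(x_{i,j}) + \epsilon)}, the local curvature of
#' the Poisson negative log-likelihood, with a small \eqn{\epsilon} guarding
#' division by zero. Columns flagged as outliers (`omega == 0`) get zero
#' weight so they do not influence the template fit.
#'
#' @param X `N x M` matrix of profile locations in \[0, 1\].
#' @param c template coefficients (used only by the Poisson model).
#' @param omega length-`M` 0/1 vector of column validity indicators.
#' @param noise `"awgn"` or `"poisson"`.
#' @param epsilon positive guard constant, default `1e-6`.
#' @return `N x M` matrix of weights.
#' @export
profile_weights <- function(X, c, omega, noise = c("awgn", "poisson"),
                            epsilon = 1e-6) {
  noise <- match.arg(noise)
  X <- as.matrix(X)
  if (noise == "awgn") {
    gam <- matrix(1, nrow(X), ncol(X))
  } else {
    fx <- matrix(eval_profile(as.vector(X), c), nrow(X), ncol(X))
    gam <- 1 / (2 * pmax(fx, 0) + epsilon)
  }
  sweep(gam, 2, omega, "*")
}

#' Template coefficient update
#'
#' One exact minimization of the alignment energy over the template
#' coefficients `c` with locations and weights held fixed: the regularized
#' weighted normal equations
#' \deqn{(\Phi \Sigma \Phi^T + \alpha \psi_L)\,c = \Phi \Sigma y,}
#' where \eqn{\Phi} collects the sinc basis evaluated at every location.
#' With the symmetry constraint (`P` supplied) the reduced system
#' \eqn{(P^T \Phi \Sigma \Phi^T P + \alpha \psi_{L/2})\,\tilde c =
#' P^T \Phi \Sigma y} is solved and `c = P %*% c_tilde` returned.
#'
#' @param X `N x M` location matrix.
#' @param Y `N x M` intensity matrix.
#' @param sigma `N x M` weight matrix from [profile_weights()].
#' @param L basis size.
#' @param alpha smoothness weight (> 0).
#' @param P optional symmetry-constraint matrix from [symmetry_matrix()].
#' @return list with `c` (length `L`) and, in symmetric mode, `c_tilde`.
#' @export
coefficient_update <- function(X, Y, sigma, L, alpha, P = NULL) {
  if (all(sigma == 0)) stop("no valid profiles: all columns are outliers")
  x <- as.vector(as.matrix(X))
  y <- as.vector(as.matrix(Y))
  s <- as.vector(as.matrix(sigma))
  phi <- sinc_basis(x, L)                         # L x NM
  A <- tcrossprod(sweep(phi, 2, s, "*"), phi)     # phi %*% diag(s) %*% t(phi)
  b <- phi %*% (s * y)
  if (is.null(P)) {
    c_hat <- solve(A + alpha * difference_penalty(L), b)
    list(c = drop(c_hat))
  } else {
    Ar <- crossprod(P, A %*% P) + alpha * difference_penalty(L / 2)
    ct <- solve(Ar, crossprod(P, b))
    list(c = drop(P %*% ct), c_tilde = drop(ct))
  }
}

#' Column outlier indicators
#'
#' A profile far from the current template is excluded from the template fit:
#' with column distances \eqn{d_j = \lVert f(x_j) - y_j \rVert_2^2}, column
#' `j` is an outlier when \eqn{d_j > \tau} with the robust threshold
#' \eqn{\tau = \mathrm{median}(d) + k \cdot 1.4826\,\mathrm{MAD}(d)}
#' (`k = outlier_factor`). The rule is re-evaluated every iteration, so a
#' column whose distance later drops below the threshold is re-admitted.
#'
#' @param Y,X `N x M` intensity and location matrices.
#' @param c template coefficients.
#' @param outlier_factor robustness multiplier, default 3.
#' @return list with `omega` (length-`M` 0/1 vector) and `d` (distances).
#' @export
outlier_update <- function(Y, X, c, outlier_factor = 3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fx <- matrix(eval_profile(as.vector(X), c), nrow(X), ncol(X))
  d <- colSums((fx - Y)^2)
  if (length(d) == 1) return(list(omega = 1, d = d))
  tau <- stats::median(d) + outlier_factor * stats::mad(d)
  omega <- as.numeric(d <= tau)
  if (all(omega == 0)) omega[which.min(d)] <- 1
  list(omega = omega, d = d, tau = tau)
}

# tridiagonal neighbour-sum operator of the fixed-point location update:
# row i sums x[i-1], x[i], x[i+1]; the border rows double the single
# interior neighbour so every row sums three terms.
location_omega_matrix <- function(N) {
  stopifnot(N >= 2)
  W <- matrix(0, N, N)
  W[cbind(1:N, 1:N)] <- 1
  if (N > 1) {
    W[cbind(1:(N - 1), 2:N)] <- 1
    W[cbind(2:N, 1:(N - 1))] <- 1
  }
  W[1, 2] <- 2
  W[N, N - 1] <- 2
  W
}

#' Location (warp) update
#'
#' One fixed-point step of the alignment energy in the observation locations:
#' \deqn{x_j^{t+1} = \tfrac{1}{3}(\Omega x_j^t - z_j / \beta),}
#' where \eqn{z_{i,j} = \gamma_{i,j} [f(x_{i,j}) - y_{i,j}] \dot f(x_{i,j})}
#' is the data force and \eqn{\Omega} the tridiagonal neighbour-sum operator,
#' so the homogeneous part moves each interior location toward the average of
#' itself and its two neighbours (the tension prior). Afterwards the column
#' endpoints are re-pinned to 0 and 1 (the warps must fix the limits, else
#' all locations could collapse to a point), and each column is projected
#' onto the monotone non-decreasing cone by a running maximum, clipped to
#' \[0, 1\]: the warps the locations estimate are monotone by assumption.
#'
#' Outlier columns keep their locations updated (`gamma`, not
#' `omega * gamma`, enters `z`), so a rejected profile can drift back toward
#' the template and be re-admitted.
#'
#' @param X,Y `N x M` location and intensity matrices.
#' @param c template coefficients.
#' @param beta tension weight (> 0).
#' @param gamma `N x M` noise weights (the \eqn{\gamma_{i,j}} part only).
#' @param step step damping factor in (0, 1\]; 1 is the full fixed-point step.
#' @return updated `N x M` location matrix.
#' @export
location_update <- function(X, Y, c, beta, gamma, step = 1) {
  stopifnot(beta > 0)
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X)
  fx <- matrix(eval_profile(as.vector(X), c), N, ncol(X))
  fdx <- matrix(eval_profile_deriv(as.vector(X), c), N, ncol(X))
  z <- gamma * (fx - Y) * fdx
  Xnew <- (location_omega_matrix(N) %*% X - z / beta) / 3
  if (step < 1) Xnew <- X + step * (Xnew - X)
  Xnew[1, ] <- 0
  Xnew[N, ] <- 1
  Xnew <- apply(Xnew, 2, cummax)
  Xnew[Xnew < 0] <- 0
  Xnew[Xnew > 1] <- 1
  Xnew
}

#' Total alignment energy
#'
#' The three-term objective minimized by [compensate()]:
#' \deqn{E(X, c, Y) = E_Y + \alpha\, c^T \psi_L c + \beta\,
#'   \mathrm{Tr}(X^T \psi_N X),}
#' with the data term \eqn{E_Y = \sum_{i,j} \omega_j (f(x_{i,j}) -
#' y_{i,j})^2} under AWGN, or the Poisson negative log-likelihood (up to a
#' `c`-free constant) \eqn{E_Y = \sum_{i,j} \omega_j [f(x_{i,j}) - y_{i,j}
#' \log f(x_{i,j})]} with `f` clipped below at `epsilon` inside the log.
#'
#' @inheritParams profile_weights
#' @param Y `N x M` intensity matrix (non-negative in Poisson mode).
#' @param alpha,beta regularization weights.
#' @return scalar energy.
#' @export
total_energy <- function(X, Y, c, omega, noise = c("awgn", "poisson"),
                         alpha, beta, epsilon = 1e-6) {
  noise <- match.arg(noise)
  X <- as.matrix(X); Y <- as.matrix(Y)
  fx <- matrix(eval_profile(as.vector(X), c), nrow(X), ncol(X))
  if (noise == "awgn") {
    ey <- sum(sweep((fx - Y)^2, 2, omega, "*"))
  } else {
    if (any(Y < 0)) stop("Poisson data term requires non-negative intensities")
    ll <- fx - Y * log(pmax(fx, epsilon))
    ey <- sum(sweep(ll, 2, omega, "*"))
  }
  ec <- alpha * sum(diff(c)^2)
  ex <- beta * sum(apply(X, 2, function(x) sum(diff(x)^2)))
  ey + ec + ex
}

#' Default alignment parameters
#'
#' @param alpha smoothness weight on the template coefficients.
#' @param beta tension weight on the location columns. The default is
#'   calibrated for intensity data on the native 8-bit-like scale
#'   (profiles peaking around 100-255 a.u.); for data rescaled to \[0, 1\]
#'   a proportionally smaller value is appropriate.
#' @param L sinc basis size (even in symmetric mode).
#' @param noise observation noise model, `"poisson"` (fluorescence default)
#'   or `"awgn"`.
#' @param symmetric constrain the template to be symmetric about 0.5
#'   (internuclear profiles); radial profiles use `FALSE`.
#' @param outlier_factor robust multiplier of the outlier threshold.
#' @param outlier_burn_in iterations before outlier rejection starts. Right
#'   after initialization the column distances measure warp magnitude rather
#'   than outlierness, so rejection only begins once the locations have had
#'   a few iterations to adapt.
#' @param epsilon division/log guard constant.
#' @param max_iter maximum alternating iterations.
#' @param tol relative-energy stopping tolerance. The Poisson data term is a
#'   log-likelihood of large magnitude, so the relative tolerance is kept
#'   tight by default.
#' @param seed reserved; the solver is deterministic.
#' @return named list of class `"alignment_params"`.
#' @export
alignment_params <- function(alpha = 1e-3, beta = 1e4, L = 20,
                             noise = c("poisson", "awgn"),
                             symmetric = TRUE, outlier_factor = 3,
                             outlier_burn_in = 50,
                             epsilon = 1e-6, max_iter = 200, tol = 1e-8,
                             seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(alpha > 0, beta > 0, L >= 4, epsilon > 0, max_iter >= 1, tol > 0,
            outlier_burn_in >= 0)
  if (symmetric && L %% 2 != 0) stop("symmetric mode requires even L")
  structure(list(alpha = alpha, beta = beta, L = L, noise = noise,
                 symmetric = symmetric, outlier_factor = outlier_factor,
                 outlier_burn_in = outlier_burn_in,
                 epsilon = epsilon, max_iter = max_iter, tol = tol,
                 seed = seed),
            class = "alignment_params")
}

#' Elastic geometric compensation of a profile stack
#'
#' Fits the generative model in which every column \eqn{y_j} of the profile
#' matrix is a warped, noisy re-sampling of one latent "ideal profile"
#' \eqn{f(x) = \varphi^T(x) c} on \[0, 1\]: alternating minimization of the
#' three-term energy (data fidelity + coefficient smoothness + location
#' tension) over the coefficients `c` and the location matrix `X`, with
#' per-column outlier rejection. Locations start uniform,
#' \eqn{x_{i,j} = i/(N-1)}, endpoints stay pinned at 0 and 1 and columns stay
#' monotone throughout. Iterations stop when the relative energy change
#' falls below `tol` (once outlier rejection has started) or after
#' `max_iter` iterations. If the energy rises for 5 consecutive iterations
#' at a stable outlier set, the location step is halved permanently (the
#' divergence guard; count in `damped`). Energy jumps at iterations where
#' the outlier set changes (`omega_changes`) reflect the changing
#' objective, not divergence.
#'
#' @param Y `N x M` numeric matrix (or [profile_matrix()]) whose columns are
#'   length-normalized intensity profiles.
#' @param params an [alignment_params()] list; individual fields may also be
#'   overridden via `...`.
#' @param init optional warm start: a previous `"compensation"` fit or a list
#'   with elements `X`, `c`, `omega`.
#' @param ... overrides for single [alignment_params()] fields.
#' @return An object of class `"compensation"`: a list with the final
#'   coefficients `c` (and `c_tilde` in symmetric mode), compensated
#'   locations `X`, outlier indicators `omega`, per-iteration `energy`
#'   trace, iteration count `iter`, convergence flag, `damped` count, the
#'   input `Y` and the fitted parameters. Methods: [print.compensation()],
#'   [summary.compensation()], [coef.compensation()],
#'   [predict.compensation()], [fitted.compensation()],
#'   [residuals.compensation()], [plot.compensation()],
#'   [simulate.compensation()]; the aligned stack itself via
#'   [compensated_map()].
#' @examples
#' f <- function(x) 20 + 80 * exp(-(x - 0.5)^2 / 0.02)
#' sim <- simulate_warped_stack(f, M = 12, N = 61, noise = "none", seed = 1)
#' fit <- compensate(sim$Y, noise = "awgn", beta = 50, symmetric = TRUE)
#' summary(fit)
#' @export
compensate <- function(Y, params = alignment_params(), init = NULL, ...) {
  over <- list(...)
  if (length(over)) {
    known <- names(formals(alignment_params))
    bad <- setdiff(names(over), known)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(over)] <- over
    params <- do.call(alignment_params, unclass(params))
  }
  meta <- attributes(Y)[c("kind", "provenance", "native_lengths")]
  Y <- as.matrix(unclass(Y))
  N <- nrow(Y); M <- ncol(Y)
  if (N < 2 || M < 1) stop("profile matrix must have >= 2 rows and >= 1 column")
  if (params$noise == "poisson" && any(Y < 0))
    stop("Poisson noise model requires non-negative intensities")

  P <- if (params$symmetric) symmetry_matrix(params$L) else NULL
  if (!is.null(init)) {
    X <- as.matrix(init$X); cc <- init$c
    omega <- init$omega %||% rep(1, M)
    stopifnot(all(dim(X) == c(N, M)))
  } else {
    X <- matrix(seq(0, 1, length.out = N), N, M)
    cc <- rep(stats::median(Y), params$L)
    # initial screen: columns grossly far from the stack (relative to the
    # robust spread of column distances) start rejected, so they never
    # distort the early template; they can re-enter once rejection resumes
    omega <- if (M >= 2) outlier_update(Y, X, cc, params$outlier_factor)$omega
             else rep(1, M)
  }

  energy <- numeric(0)
  omega_changes <- logical(0)
  damped <- 0L
  inc_run <- 0L
  step_damp <- 1
  converged <- FALSE
  e_prev <- NA_real_
  iter <- 0L

  for (t in seq_len(params$max_iter)) {
    iter <- t
    # alternate the template fit and the outlier indicators to a joint
    # fixed point, so flags are never left over from a template that was
    # still distorted by the very columns being rejected; during the
    # burn-in the indicators stay frozen
    omega_new <- omega
    c_new <- cc
    for (r in 1:10) {
      sig <- profile_weights(X, cc, omega_new, params$noise, params$epsilon)
      c_new <- coefficient_update(X, Y, sig, params$L, params$alpha, P)$c
      if (t <= params$outlier_burn_in) break
      ou <- outlier_update(Y, X, c_new, params$outlier_factor)
      if (identical(ou$omega, omega_new)) break
      omega_new <- ou$omega
    }
    omega_changed <- !identical(omega_new, omega)
    gam <- profile_weights(X, c_new, rep(1, M), params$noise, params$epsilon)

    cc <- c_new
    X <- location_update(X, Y, cc, params$beta, gam, step = step_damp)
    omega <- omega_new
    e_try <- total_energy(X, Y, cc, omega, params$noise,
                          params$alpha, params$beta, params$epsilon)
    # divergence guard: the fixed-point location step has no step-size
    # guarantee, so a persistent energy rise (5 consecutive iterations at a
    # stable outlier set) halves the location step for good
    if (!omega_changed && !is.na(e_prev) && e_try > e_prev) {
      inc_run <- inc_run + 1L
      if (inc_run >= 5L) {
        step_damp <- max(step_damp / 2, 1 / 64)
        damped <- damped + 1L
        inc_run <- 0L
      }
    } else inc_run <- 0L
    energy <- c(energy, e_try)
    omega_changes <- c(omega_changes, omega_changed)
    if (t > params$outlier_burn_in + 1 && !is.na(e_prev) &&
        abs(e_try - e_prev) <= params$tol * abs(e_prev)) {
      converged <- TRUE
      break
    }
    e_prev <- e_try
  }

  fit <- structure(list(
    c = cc,
    c_tilde = if (params$symmetric) drop(crossprod(symmetry_matrix(params$L),
                                                   cc)) / 2 else NULL,
    X = X, omega = omega, energy = energy,
    omega_changes = omega_changes, iter = iter,
    converged = converged, damped = damped,
    Y = Y, params = params,
    kind = meta$kind %||% NA_character_,
    provenance = meta$provenance
  ), class = "compensation")
  fit
}

#' Aligned (compensated) profile map
#'
#' Re-samples every profile column at its estimated true locations back onto
#' the uniform grid `i/(N-1)`: for column `j`, the pairs
#' \eqn{(x^*_{i,j}, y_{i,j})} are interpolated by a monotone (piecewise
#' linear) interpolant, tied locations averaged first, and evaluated on the
#' uniform grid. Outlier columns are retained in the map (flagged in the
#' `omega` attribute).
#'
#' @param fit a `"compensation"` object.
#' @param Y optional profile matrix to resample (defaults to the fitted one).
#' @return `N x M` aligned matrix with attribute `omega`.
#' @export
compensated_map <- function(fit, Y = NULL) {
  stopifnot(inherits(fit, "compensation"))
  Y <- as.matrix(Y %||% fit$Y)
  X <- fit$X
  N <- nrow(Y)
  grid <- seq(0, 1, length.out = N)
  out <- matrix(NA_real_, N, ncol(Y))
  for (j in seq_len(ncol(Y))) {
    xj <- X[, j]
    if (is.unsorted(xj)) stop("non-monotone location column ", j)
    out[, j] <- resample_monotone(xj, Y[, j], grid)
  }
  attr(out, "omega") <- fit$omega
  out
}

# monotone (piecewise-linear) resampling of (x, y) onto grid; locations
# closer than tol are collapsed by mean, so running-max plateaus from the
# monotonicity projection become single knots
resample_monotone <- function(x, y, grid, tol = 1e-9) {
  grp <- cumsum(c(TRUE, diff(x) > tol))
  xu <- as.numeric(tapply(x, grp, mean))
  yu <- as.numeric(tapply(y, grp, mean))
  if (length(xu) < 2) return(rep(yu[1], length(grid)))
  stats::approx(xu, yu, xout = grid, rule = 2)$y
}
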