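#' @export
print.compensation <- function(x, ...) {
  p <- x$params
  cat("Elastic geometric compensation fit\n")
  cat(sprintf("  profiles: %d x %d (%s)\n", nrow(x$Y), ncol(x$Y),
              if (is.na(x$kind)) "unlabelled" else x$kind))
  cat(sprintf("  noise model: %s | basis L = %d%s | alpha = %g, beta = %g\n",
              p$noise, p$L, if (p$symmetric) " (symmetric)" else "",
              p$alpha, p$beta))
  cat(sprintf("  iterations: %d (%s), final energy %.6g, %d outlier column(s)\n",
              x$iter, if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$energy, 1), sum(x$omega == 0)))
  invisible(x)
}

#' Summarize a compensation fit
#'
#' Row-wise mean and standard deviation of the compensated map over the
#' valid (non-outlier) columns, plus the peak of the mean curve. Positions
#' are reported 0-based (`0 ... N-1`), so with the default 101-sample
#' normalization the internuclear midpoint is position 50.
#'
#' @param object a `"compensation"` fit.
#' @param ... unused.
#' @return object of class `"profile_summary"`: list with `position`, `mean`,
#'   `sd`, `peak_position`, `peak_value`, `n_profiles_used`.
#' @export
summary.compensation <- function(object, ...) {
  map <- compensated_map(object)
  out <- summarize_map(map, object$omega)
  out$kind <- object$kind
  out
}

#' Row-wise summary of a profile map
#'
#' @param map `N x M` matrix (aligned or raw profile stack).
#' @param omega optional 0/1 column validity vector; only `omega == 1`
#'   columns enter the statistics.
#' @return object of class `"profile_summary"`.
#' @export
summarize_map <- function(map, omega = NULL) {
  map <- as.matrix(map)
  omega <- omega %||% attr(map, "omega") %||% rep(1, ncol(map))
  keep <- omega == 1
  if (!any(keep)) stop("all columns excluded: nothing to summarize")
  m <- map[, keep, drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  if (ncol(m) == 1) sdv <- rep(0, nrow(m))
  peak <- which.max(mu)  # which.max returns the first (smallest) index on ties
  structure(list(position = seq_len(nrow(m)) - 1L, mean = mu, sd = sdv,
                 peak_position = peak - 1L, peak_value = mu[peak],
                 n_profiles_used = ncol(m)),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Profile summary (positions 0-based)\n")
  cat(sprintf("  samples per profile: %d | profiles used: %d\n",
              length(x$mean), x$n_profiles_used))
  cat(sprintf("  peak: %.2f a.u. at position %d\n",
              x$peak_value, x$peak_position))
  invisible(x)
}

#' @export
coef.compensation <- function(object, ...) object$c

#' Evaluate the fitted ideal profile
#'
#' @param object a `"compensation"` fit.
#' @param newdata numeric vector of locations in \[0, 1\]; defaults to the
#'   uniform grid of the fitted stack.
#' @param ... unused.
#' @return numeric vector `f(newdata)`.
#' @export
predict.compensation <- function(object, newdata = NULL, ...) {
  x <- newdata %||% seq(0, 1, length.out = nrow(object$Y))
  eval_profile(x, object$c)
}

#' @export
fitted.compensation <- function(object, ...) {
  matrix(eval_profile(as.vector(object$X), object$c),
         nrow(object$X), ncol(object$X))
}

#' @export
residuals.compensation <- function(object, ...) {
  object$Y - fitted(object)
}

#' Diagnostic plots for a compensation fit
#'
#' Draws the raw and compensated mean +/- SD curves, the fitted ideal
#' profile, and the energy trace.
#'
#' @param x a `"compensation"` fit.
#' @param which subset of `1:3` selecting panels.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.compensation <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  grid <- seq(0, 1, length.out = nrow(x$Y))
  if (1 %in% which) {
    raw <- summarize_map(x$Y, x$omega)
    graphics::matplot(raw$position, cbind(raw$mean - raw$sd, raw$mean,
                                          raw$mean + raw$sd),
                      type = "l", lty = c(2, 1, 2), col = "grey40",
                      xlab = "position", ylab = "intensity (a.u.)",
                      main = "raw profiles", ...)
  }
  if (2 %in% which) {
    s <- summary(x)
    graphics::matplot(s$position, cbind(s$mean - s$sd, s$mean, s$mean + s$sd),
                      type = "l", lty = c(2, 1, 2), col = "black",
                      xlab = "position", ylab = "intensity (a.u.)",
                      main = "compensated", ...)
    graphics::lines((length(grid) - 1) * grid, predict(x), col = 2)
  }
  if (3 %in% which) {
    graphics::plot(seq_along(x$energy), x$energy, type = "b", log = "y",
                   xlab = "iteration", ylab = "energy", main = "energy trace")
  }
  invisible(x)
}

#' Simulate new profile stacks from a fitted template
#'
#' Draws `nsim` synthetic profile matrices whose columns are random monotone
#' warps of the fitted ideal profile plus observation noise under the
#' fitted noise model — the generative model the compensation fit assumes.
#'
#' @param object a `"compensation"` fit.
#' @param nsim number of stacks.
#' @param seed integer seed.
#' @param M columns per stack (default: as fitted).
#' @param warp_amp warp amplitude passed to [simulate_warped_stack()].
#' @param ... unused.
#' @return list of `N x M` matrices (length `nsim`).
#' @export
simulate.compensation <- function(object, nsim = 1, seed = NULL,
                                  M = ncol(object$Y), warp_amp = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- function(x) pmax(eval_profile(x, object$c), 0)
  noise <- if (object$params$noise == "poisson") "poisson" else "awgn"
  lapply(seq_len(nsim), function(i)
    simulate_warped_stack(f, M = M, N = nrow(object$Y), noise = noise,
                          warp_amp = warp_amp,
                          seed = sample.int(.Machine$integer.max, 1))$Y)
}
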