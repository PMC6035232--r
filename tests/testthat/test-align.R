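band_limited_stack <- function(L = 12, N = 101, M = 10, seed = 2) {
  set.seed(seed)
  cc <- 20 + 5 * abs(rnorm(L))
  cc <- (cc + rev(cc)) / 2
  x <- seq(0, 1, length.out = N)
  list(c = cc, x = x, Y = matrix(eval_profile(x, cc), N, M))
}

test_that("weights follow the noise model and outlier indicators", {
  X <- matrix(seq(0, 1, length.out = 11), 11, 4)
  cc <- rep(2, 8)
  w <- profile_weights(X, cc, rep(1, 4), "awgn")
  expect_true(all(w == 1))

  w0 <- profile_weights(X, rep(0, 8), rep(1, 4), "poisson", epsilon = 1e-6)
  expect_equal(w0[1, 1], 1e6)

  wo <- profile_weights(X, cc, c(1, 0, 1, 1), "awgn")
  expect_true(all(wo[, 2] == 0) && all(wo[, -2] == 1))
})

test_that("coefficient update recovers a band-limited generator exactly", {
  bl <- band_limited_stack()
  sig <- matrix(1, 101, 10)
  X <- matrix(bl$x, 101, 10)
  up <- coefficient_update(X, bl$Y, sig, 12, alpha = 1e-12)
  expect_lt(max(abs(up$c - bl$c)), 1e-6)

  # infinite smoothing drives the coefficients to a constant vector
  up_inf <- coefficient_update(X, bl$Y, sig, 12, alpha = 1e12)
  expect_lt(diff(range(up_inf$c)), 1e-3 * mean(up_inf$c))

  # symmetric mode is mirror-exact by construction
  up_sym <- coefficient_update(X, bl$Y + rnorm(1010), sig, 12, alpha = 1e-3,
                               P = symmetry_matrix(12))
  expect_identical(up_sym$c, rev(up_sym$c))

  expect_error(coefficient_update(X, bl$Y, sig * 0, 12, 1e-3),
               "no valid profiles")
})

test_that("coefficient update satisfies the stationarity condition", {
  set.seed(4)
  N <- 61; M <- 8; L <- 10
  X <- matrix(seq(0, 1, length.out = N), N, M)
  Y <- matrix(50 + rnorm(N * M, sd = 5), N, M)
  sig <- matrix(runif(N * M, 0.5, 1.5), N, M)
  up <- coefficient_update(X, Y, sig, L, alpha = 0.5)
  g <- coef_gradient_awgn(X, Y, up$c, sig, 0.5)
  expect_lt(sqrt(sum(g^2)), 1e-6 * sqrt(sum(up$c^2)))
})

test_that("outlier indicators reject garbage and re-admit coherent columns", {
  bl <- band_limited_stack(M = 12)
  X <- matrix(bl$x, 101, 12)
  ou <- outlier_update(bl$Y, X, bl$c)
  expect_true(all(ou$omega == 1))

  Yd <- bl$Y
  Yd[, 5] <- 10 * diff(range(bl$Y)) + max(bl$Y)
  oud <- outlier_update(Yd, X, bl$c)
  expect_equal(oud$omega[5], 0)
  expect_true(all(oud$omega[-5] == 1))
  expect_gt(oud$d[5], oud$tau)  # the rule fires on the distance itself

  # column replaced by coherent data falls below tau and re-enters
  Yd[, 5] <- bl$Y[, 5]
  our <- outlier_update(Yd, X, bl$c)
  expect_equal(our$omega[5], 1)

  expect_equal(outlier_update(bl$Y[, 1, drop = FALSE], X[, 1, drop = FALSE],
                              bl$c)$omega, 1)
})

test_that("the location operator matches the printed tridiagonal form", {
  expect_equal(profilecomp:::location_omega_matrix(4),
               rbind(c(1, 2, 0, 0), c(1, 1, 1, 0),
                     c(0, 1, 1, 1), c(0, 0, 2, 1)))
})

test_that("location update fixes uniform spacing and restores it for flat f", {
  N <- 21; M <- 5
  X <- matrix(seq(0, 1, length.out = N), N, M)
  cc <- rep(4, 10)
  # y = f(x) exactly, so the data force z vanishes: uniform X is a fixed
  # point of the interior update
  Y <- matrix(eval_profile(X[, 1], cc), N, M)
  gam <- matrix(1, N, M)
  Xn <- location_update(X, Y, cc, beta = 10, gam)
  expect_equal(Xn, X, tolerance = 1e-9)

  # with no data force (flat template: z = 0), a distorted start relaxes
  # back to uniform spacing under iteration
  set.seed(1)
  Xd <- apply(matrix(runif(N * M), N, M), 2, function(u) {
    v <- sort(u); (v - v[1]) / (v[N] - v[1])
  })
  zero <- matrix(0, N, M)
  for (i in 1:3000) Xd <- location_update(Xd, Y, cc, beta = 10, zero)
  expect_lt(max(abs(Xd - X)), 1e-3)
})

test_that("location columns stay monotone, pinned and inside [0,1]", {
  set.seed(8)
  N <- 31; M <- 6
  X <- matrix(seq(0, 1, length.out = N), N, M)
  Y <- matrix(runif(N * M) * 100, N, M)
  cc <- rnorm(16) * 50
  gam <- matrix(1, N, M)
  for (i in 1:25) {
    X <- location_update(X, Y, cc, beta = 500, gam)
    expect_true(all(X >= 0 & X <= 1))
    expect_true(all(X[1, ] == 0) && all(X[N, ] == 1))
    expect_true(all(apply(X, 2, function(v) !is.unsorted(v))))
  }
})

test_that("total energy reduces to its closed forms", {
  bl <- band_limited_stack(M = 6)
  N <- 101; M <- 6
  X <- matrix(bl$x, N, M)
  cc0 <- rep(30, 12)
  Y0 <- matrix(eval_profile(bl$x, cc0), N, M)
  # perfect fit (y = f(x)), constant c: only the tension term remains,
  # beta * M / (N - 1) for uniform locations
  e <- total_energy(X, Y0, cc0, rep(1, M), "awgn", alpha = 2, beta = 7)
  expect_equal(e, 7 * M / (N - 1), tolerance = 1e-9)

  # alpha = beta = 0: plain weighted residual sum of squares
  e0 <- total_energy(X, bl$Y + 1, bl$c, rep(1, M), "awgn", 0, 0)
  expect_equal(e0, sum((matrix(eval_profile(bl$x, bl$c), N, M) -
                        (bl$Y + 1))^2), tolerance = 1e-9)

  # zero image, zero template, Poisson: data term vanishes
  ez <- total_energy(X, matrix(0, N, M), rep(0, 12), rep(1, M), "poisson",
                     0, 0)
  expect_equal(ez, 0, tolerance = 1e-9)

  expect_error(total_energy(X, matrix(-1, N, M), bl$c, rep(1, M), "poisson",
                            1, 1), "non-negative")
})

test_that("compensation is self-consistent on identical noiseless columns", {
  bl <- band_limited_stack()
  fit <- compensate(bl$Y, noise = "awgn", L = 12, alpha = 1e-8,
                    symmetric = TRUE, max_iter = 60)
  expect_lt(sqrt(mean((predict(fit) - bl$Y[, 1])^2)), 1e-4)
  expect_lt(max(abs(fit$X - bl$x)), 1e-6)
  expect_true(all(fit$omega == 1))
  expect_identical(coef(fit), rev(coef(fit)))   # mirror-exact
})

test_that("monotone warps of a noiseless template are compensated away", {
  bl <- band_limited_stack()
  f <- function(x) eval_profile(x, bl$c)
  sim <- simulate_warped_stack(f, M = 30, N = 101, noise = "none", seed = 1)
  fit <- compensate(sim$Y, noise = "awgn", L = 12, alpha = 1e-8,
                    symmetric = TRUE, max_iter = 300)
  map <- compensated_map(fit)
  v_before <- mean(apply(sim$Y, 1, var))
  v_after <- mean(apply(map, 1, var))
  expect_lt(v_after, 0.10 * v_before)
})

test_that("single-column input returns a smoothed fit with omega = 1", {
  set.seed(9)
  y <- matrix(50 + 20 * sin(seq(0, pi, length.out = 51)) + rnorm(51), ncol = 1)
  fit <- compensate(y, noise = "awgn", symmetric = FALSE, max_iter = 30)
  expect_equal(fit$omega, 1)
  expect_equal(length(coef(fit)), 20)
})

test_that("compensated map is the identity at uniform locations", {
  bl <- band_limited_stack(M = 4)
  fit <- compensate(bl$Y, noise = "awgn", L = 12, symmetric = FALSE,
                    max_iter = 2)
  fit$X <- matrix(bl$x, 101, 4)
  expect_equal(compensated_map(fit), bl$Y, ignore_attr = TRUE,
               tolerance = 1e-9)

  Yc <- matrix(6, 101, 4)
  fitc <- compensate(Yc, noise = "awgn", symmetric = FALSE, max_iter = 5)
  expect_equal(unique(as.vector(compensated_map(fitc))), 6, tolerance = 1e-6)
})

test_that("fit methods expose coefficients, residuals and simulations", {
  bl <- band_limited_stack(M = 5)
  fit <- compensate(bl$Y + matrix(rnorm(505), 101), noise = "awgn", L = 12,
                    symmetric = TRUE, max_iter = 30)
  expect_length(coef(fit), 12)
  expect_equal(dim(residuals(fit)), c(101, 5))
  expect_equal(fitted(fit) + residuals(fit), fit$Y, tolerance = 1e-12)
  expect_equal(predict(fit, c(0.25, 0.75)),
               eval_profile(c(0.25, 0.75), coef(fit)))
  sims <- simulate(fit, nsim = 2, seed = 1, M = 4)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(101, 4))
})
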