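# Independent oracles used across tests.

# Brute-force Delaunay: a triangle belongs to the triangulation iff no other
# point lies strictly inside its circumcircle.
brute_force_delaunay <- function(pts) {
  n <- nrow(pts)
  out <- NULL
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    tx <- pts[c(a, b, cc), 2]; ty <- pts[c(a, b, cc), 1]
    d <- 2 * ((tx[2] - tx[1]) * (ty[3] - ty[1]) -
              (ty[2] - ty[1]) * (tx[3] - tx[1]))
    if (abs(d) < 1e-12) next
    s1 <- tx[2]^2 - tx[1]^2 + ty[2]^2 - ty[1]^2
    s2 <- tx[3]^2 - tx[1]^2 + ty[3]^2 - ty[1]^2
    ux <- (s1 * (ty[3] - ty[1]) - s2 * (ty[2] - ty[1])) / d
    uy <- (s2 * (tx[2] - tx[1]) - s1 * (tx[3] - tx[1])) / d
    r2 <- (tx[1] - ux)^2 + (ty[1] - uy)^2
    others <- setdiff(1:n, c(a, b, cc))
    if (all((pts[others, 2] - ux)^2 + (pts[others, 1] - uy)^2 >
            r2 * (1 - 1e-9)))
      out <- rbind(out, c(a, b, cc))
  }
  out
}

tri_key <- function(tri) sort(apply(tri, 1, paste, collapse = "-"))

# membrane-prototype template used by the warped-stack checks: sharp
# symmetric peak at the profile midpoint over a low baseline, peak height
# ~100 a.u. over base 20 (Poisson counting scale)
membrane_template <- function(x) 20 + 140 * exp(-(x - 0.5)^2 / (2 * 0.05^2))

# 50 jittered near-equilateral triangles plus one 179-degree sliver,
# assembled directly as a triangle list
sliver_case <- function(seed = 5) {
  set.seed(seed)
  unit <- rbind(c(0, 0), c(0, 10), c(10 * sin(pi / 3), 5))
  pts <- do.call(rbind, lapply(1:50, function(i) {
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    sweep(unit %*% R, 2, runif(2, 0, 200), "+") +
      matrix(runif(6, -0.3, 0.3), 3)
  }))
  pts <- rbind(pts, c(100, 0), c(100.2, 20), c(100, 40))
  tris <- matrix(seq_len(153), ncol = 3, byrow = TRUE)
  list(pts = pts, tris = tris, sliver_tri = 51,
       pr = prune_obtuse_triangles(pts, tris))
}

# analytic energy gradient in the coefficients (AWGN), the stationarity
# condition the coefficient update must satisfy
coef_gradient_awgn <- function(X, Y, cc, sigma, alpha) {
  x <- as.vector(X); y <- as.vector(Y); s <- as.vector(sigma)
  phi <- sinc_basis(x, length(cc))
  drop((tcrossprod(sweep(phi, 2, s, "*"), phi) +
        alpha * difference_penalty(length(cc))) %*% cc - phi %*% (s * y))
}
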