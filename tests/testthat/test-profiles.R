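circle_boundary <- function(center, radius, n = 720) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
}

test_that("beam endpoints follow the affine sweep between the two chords", {
  bA <- circle_boundary(c(0, 0), 5)
  bB <- circle_boundary(c(0, 20), 5)
  beam <- in_beam_endpoints(bA, bB, c(0, 0), c(0, 20), n = 10)
  # chord of A: perpendicular to the (col-direction) axis -> rows +-5
  expect_equal(sort(beam$chord_A[, 1]), c(-5, 5), tolerance = 1e-3)
  expect_equal(beam$chord_A[, 2], c(0, 0), tolerance = 1e-3)
  expect_equal(sort(beam$chord_B[, 1]), c(-5, 5), tolerance = 1e-3)
  expect_equal(beam$m, 20)

  # start/end points are affine in the line index (vanishing 2nd difference)
  expect_lt(max(abs(diff(diff(beam$starts)))), 1e-9)
  expect_lt(max(abs(diff(diff(beam$ends)))), 1e-9)
  # line i runs from A's diameter to B's diameter at the same fraction
  expect_equal(beam$starts[1, ], beam$chord_A[1, ], tolerance = 1e-9)
  expect_equal(beam$starts[10, ], beam$chord_A[2, ], tolerance = 1e-9)
  expect_equal(beam$ends[1, ], beam$chord_B[1, ], tolerance = 1e-9)

  # midpoint of a 3-line beam sits halfway along each chord
  b3 <- in_beam_endpoints(bA, bB, c(0, 0), c(0, 20), n = 3)
  expect_equal(b3$starts[2, ], colMeans(b3$chord_A), tolerance = 1e-9)

  expect_error(in_beam_endpoints(bA, bA, c(0, 0), c(0, 0)), "coincident")
})

test_that("profile sampling is exact on constant and linear fields", {
  const <- matrix(7, 40, 40)
  p <- sample_profile(const, c(5, 5), c(30, 22), 25)
  expect_equal(as.numeric(p), rep(7, 25), tolerance = 1e-12)

  ramp <- matrix(0:39, 40, 40, byrow = TRUE)  # I(r, c) = c
  p <- sample_profile(ramp, c(3, 0), c(3, 10), 11)
  expect_equal(as.numeric(p), 0:10, tolerance = 1e-9)

  expect_error(sample_profile(const, c(5, 5), c(5, 5), 10), "start equals end")
})

test_that("length normalization preserves endpoints, lines and symmetry", {
  p <- sin(seq(0, pi, length.out = 37)) * 12
  expect_equal(normalize_length(p, 37), p, tolerance = 1e-9)

  lin <- seq(2, 9, length.out = 13)
  out <- normalize_length(lin, 51)
  expect_equal(out, seq(2, 9, length.out = 51), tolerance = 1e-9)

  tri <- normalize_length(c(0, 1, 0), 5)
  expect_equal(tri, rev(tri), tolerance = 1e-12)
  expect_equal(which.max(tri), 3)
  expect_equal(tri[c(1, 5)], c(0, 0), tolerance = 1e-12)

  expect_error(normalize_length(3, 5), "too short")

  # overshoot of the cubic resampler stays within 5% of the range
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1), 0, 100)
    q <- normalize_length(p, 101)
    expect_lte(max(q) - max(p), 0.05 * diff(range(p)))
    expect_lte(min(p) - min(q), 0.05 * diff(range(p)))
  }
})

test_that("the neighbourhood spline interpolates and stays near circles", {
  center <- c(0, 0)
  compass <- rbind(c(10, 0), c(-10, 0), c(0, 10), c(0, -10))
  sp <- rd_boundary_spline(center, compass, n_out = 2048)
  for (k in 1:4) {
    d <- sqrt(rowSums(sweep(sp, 2, compass[k, ])^2))
    expect_lt(min(d), 0.05)
  }

  th <- 2 * pi * (0:7) / 8
  ring <- cbind(12 * sin(th), 12 * cos(th))
  sp <- rd_boundary_spline(center, ring)
  r <- sqrt(rowSums(sp^2))
  expect_true(all(r >= 0.9 * 12 & r <= 1.1 * 12))

  expect_error(rd_boundary_spline(center, ring[1:2, ]), ">= 3")
})

test_that("radial fans have equi-spaced angles and exact ray lengths", {
  th <- 2 * pi * (0:255) / 256
  circle <- cbind(10 * sin(th), 10 * cos(th))
  img <- matrix(5, 64, 64)
  fan <- rd_profiles(img, c(31, 31), sweep(circle, 2, c(31, 31), "+"), m = 12)
  expect_true(all(fan$lengths == 10))
  expect_equal(diff(fan$angles), rep(2 * pi / 12, 11), tolerance = 1e-12)
  for (p in fan$profiles) expect_equal(as.numeric(p), rep(5, length(p)))

  # square neighbourhood, rays along the axes hit the mid-edges at 10
  sq <- rbind(c(-10, -10), c(-10, 10), c(10, 10), c(10, -10),
              c(-10, -10))
  dense <- do.call(rbind, lapply(1:4, function(s) {
    t <- seq(0, 1, length.out = 200)[-200]
    outer(1 - t, sq[s, ]) + outer(t, sq[s + 1, ])
  }))
  fan <- rd_profiles(img, c(31, 31), sweep(dense, 2, c(31, 31), "+"), m = 4)
  expect_true(all(fan$lengths == 10))

  # centroid outside the curve: no intersection for some ray
  expect_error(
    rd_profiles(img, c(5, 5), sweep(circle, 2, c(40, 40), "+"), m = 8),
    "does not intersect")
})

test_that("profile matrices assemble with counts, kinds and provenance", {
  profs <- lapply(1:30, function(i) runif(sample(20:60, 1)) * 100)
  pm <- assemble_matrix(profs, N = 101, kind = "in")
  expect_equal(dim(pm), c(101, 30))
  expect_equal(attr(pm, "kind"), "in")
  expect_equal(length(attr(pm, "native_lengths")), 30)

  one <- assemble_matrix(list(runif(10)), N = 21, kind = "rd")
  expect_equal(ncol(one), 1)

  mixed <- list(structure(runif(10), kind = "in"),
                structure(runif(10), kind = "rd"))
  expect_error(assemble_matrix(mixed, N = 21, kind = "in"), "mix")
  expect_error(assemble_matrix(list(), N = 21, kind = "in"), "no profiles")
})

test_that("IN columns peak near the membrane crossing on noiseless images", {
  scene <- membrane_scene()
  pm <- extract_in_profiles(scene$sample$marker_channel, scene$net,
                            scene$seg, n = 10, N = 101)
  prov <- attr(pm, "provenance")
  regions <- scene$sample$cell_regions
  nodes <- scene$net$nodes
  beams <- list()
  checked <- 0
  for (j in seq_len(ncol(pm))) {
    key <- paste(prov$pair_a[j], prov$pair_b[j])
    if (is.null(beams[[key]]))
      beams[[key]] <- in_beam_endpoints(
        scene$seg$boundaries[[prov$pair_a[j]]],
        scene$seg$boundaries[[prov$pair_b[j]]],
        nodes[prov$pair_a[j], ], nodes[prov$pair_b[j], ], n = 10)
    beam <- beams[[key]]
    i <- prov$line[j] + 1
    tseq <- seq(0, 1, length.out = 101)
    px <- round(cbind(
      beam$starts[i, 1] + tseq * (beam$ends[i, 1] - beam$starts[i, 1]),
      beam$starts[i, 2] + tseq * (beam$ends[i, 2] - beam$starts[i, 2]))) + 1
    px[px < 1] <- 1
    px[, 1] <- pmin(px[, 1], nrow(regions)); px[, 2] <- pmin(px[, 2], ncol(regions))
    labs <- regions[px]
    if (length(unique(labs)) != 2) next  # line grazes a third cell
    truth <- which(labs != labs[1])[1] - 1
    expect_lte(abs((which.max(pm[, j]) - 1) - truth), 3)
    checked <- checked + 1
    if (checked >= 80) break
  }
  expect_gte(checked, 30)
})

test_that("profile matrices round-trip through the CSV container", {
  scene <- membrane_scene()
  pm <- extract_in_profiles(scene$sample$marker_channel, scene$net,
                            scene$seg, n = 3, N = 31)
  path <- tempfile(fileext = ".csv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_equal(unclass(back), unclass(pm), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(attr(back, "kind"), "in")
  expect_equal(attr(back, "provenance")$pair_a, attr(pm, "provenance")$pair_a)
  expect_equal(attr(back, "native_lengths"), attr(pm, "native_lengths"))
})
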