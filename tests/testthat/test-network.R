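disc_image <- function(centers, radius = 9, size = 96) {
  img <- matrix(10, size, size)
  rows <- matrix(0:(size - 1), size, size)
  cols <- matrix(0:(size - 1), size, size, byrow = TRUE)
  for (k in seq_len(nrow(centers)))
    img[(rows - centers[k, 1])^2 + (cols - centers[k, 2])^2 <= radius^2] <- 200
  img
}

test_that("preprocessing is a monotone, scale-invariant percentile stretch", {
  img <- disc_image(rbind(c(30, 30)))
  out <- preprocess(img)
  expect_equal(range(out), c(0, 255))
  expect_equal(preprocess(img * 0.5), out)    # scale invariance
  # monotone: pixel ordering preserved
  set.seed(1)
  m <- matrix(runif(400) * 90 + 10, 20)
  expect_true(all(diff(preprocess(m)[order(m)]) >= -1e-9))
  expect_warning(p <- preprocess(matrix(5, 10, 10)), "constant")
  expect_equal(p, matrix(5, 10, 10))
})

test_that("segmentation finds disc centres to sub-pixel accuracy", {
  centers <- rbind(c(30, 25), c(70, 60))
  seg <- segment_nuclei(disc_image(centers))
  expect_equal(nrow(seg$records), 2)
  found <- as.matrix(seg$records[order(seg$records$row), c("row", "col")])
  expect_lt(max(abs(found - centers)), 0.5)
  expect_error(segment_nuclei(matrix(0, 50, 50)), "no nuclei")
  # speck filtering
  img <- disc_image(rbind(c(30, 30)))
  img[5, 5] <- 220
  expect_equal(nrow(segment_nuclei(img, min_area = 30)$records), 1)
})

test_that("boundary traces are closed chains of true boundary pixels", {
  seg <- segment_nuclei(disc_image(rbind(c(40, 40)), radius = 12))
  b <- seg$boundaries[[1]]
  expect_gte(nrow(b), 8)
  # chain steps are 8-connected
  steps <- abs(diff(b))
  expect_true(all(steps <= 1))
  # every traced pixel belongs to the component and touches the background
  lab <- seg$labels
  for (i in seq_len(nrow(b))) {
    p <- b[i, ] + 1
    expect_equal(lab[p[1], p[2]], 1)
  }
})

test_that("Delaunay triangulation matches classic cases and the oracle", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  net <- build_network(sq, prune = FALSE)
  expect_equal(nrow(net$triangles), 2)
  expect_equal(nrow(net$edges), 5)

  col <- delaunay_triangulation(cbind(0:2, 0:2))
  expect_equal(nrow(col$triangles), 0)
  expect_true(col$degenerate)

  th <- 2 * pi * (0:5) / 6
  hexc <- rbind(cbind(sin(th), cos(th)), c(0, 0))
  dt <- delaunay_triangulation(hexc)
  expect_equal(nrow(dt$triangles), 6)
  expect_equal(tri_key(dt$triangles), tri_key(brute_force_delaunay(hexc)))

  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(runif(30) * 100, ncol = 2)
    dt <- delaunay_triangulation(pts)
    expect_equal(tri_key(dt$triangles), tri_key(brute_force_delaunay(pts)))
  }
})

test_that("obtuse-triangle pruning fires on slivers and only on slivers", {
  # congruent triangles: zero SD, nothing removed
  grid <- as.matrix(expand.grid(r = 0:3, c = 0:3))
  dt <- delaunay_triangulation(grid)
  pr <- prune_obtuse_triangles(grid, dt$triangles)
  expect_equal(nrow(pr$removed), 0)

  # one 179-degree sliver among ~50 near-equilateral triangles
  sl <- sliver_case()
  expect_gt(sl$pr$phi[sl$sliver_tri],
            mean(sl$pr$phi) + 3 * sd(sl$pr$phi))
  expect_true(any(apply(sl$pr$removed, 1, function(v)
    all(v == sl$tris[sl$sliver_tri, ]))))
  expect_equal(nrow(sl$pr$removed), 1)
  expect_match(sl$pr$reason, "angle")

  # a single triangle is always kept (SD undefined)
  one <- rbind(c(0, 0), c(0, 10), c(10, 0))
  pr1 <- prune_obtuse_triangles(one, matrix(c(1, 2, 3), 1))
  expect_equal(nrow(pr1$kept), 1)

  # pruning is invariant to triangle ordering
  sl <- sliver_case()
  perm <- sample(nrow(sl$tris))
  pr2 <- prune_obtuse_triangles(sl$pts, sl$tris[perm, ])
  expect_equal(tri_key(sl$pr$kept), tri_key(pr2$kept))
})

test_that("networks handle tiny inputs and keep edges consistent", {
  two <- rbind(c(0, 0), c(10, 10))
  net <- build_network(two)
  expect_equal(net$edges, matrix(c(1L, 2L), 1, 2))
  expect_equal(nrow(net$triangles), 0)
  expect_error(build_network(rbind(c(0, 0))), "at least 2")

  scene <- membrane_scene()
  net <- scene$net
  # kept triangles are a subset of the Delaunay set
  full <- delaunay_triangulation(net$nodes)
  expect_true(all(tri_key(net$triangles) %in% tri_key(full$triangles)))
  # edges unique and undirected (stored with smaller label first)
  expect_true(all(net$edges[, 1] < net$edges[, 2]))
  expect_equal(nrow(unique(net$edges)), nrow(net$edges))
  # every edge belongs to a kept triangle
  te <- unique(do.call(rbind, lapply(seq_len(nrow(net$triangles)), function(t) {
    v <- net$triangles[t, ]
    rbind(v[1:2], v[2:3], v[c(1, 3)])
  })))
  expect_true(all(paste(net$edges[, 1], net$edges[, 2]) %in%
                  paste(te[, 1], te[, 2])))
})
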