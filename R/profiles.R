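#' Sub-pixel bicubic image sampling
#'
#' Evaluates a 2-D intensity grid at arbitrary sub-pixel positions with the
#' Keys bicubic convolution kernel (a = -1/2), which reproduces linear
#' fields exactly. Coordinates are 0-based `(row, col)` with pixel centers
#' at integers; positions outside the frame are clamped to the border.
#'
#' @param image numeric matrix.
#' @param coords `p x 2` matrix of `(row, col)` positions.
#' @return numeric vector of length `p`.
#' @export
bicubic_sample <- function(image, coords) {
  coords <- matrix(coords, ncol = 2)
  H <- nrow(image); W <- ncol(image)
  r <- pmin(pmax(coords[, 1], 0), H - 1)
  c <- pmin(pmax(coords[, 2], 0), W - 1)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- numeric(length(r))
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 0), H - 1) + 1
    wr <- keys_kernel(fr - i)
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 0), W - 1) + 1
      wc <- keys_kernel(fc - j)
      out <- out + wr * wc * image[cbind(ri, cj)]
    }
  }
  out
}

# Keys cubic convolution kernel, a = -1/2
keys_kernel <- function(t) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (1.5 * t[i1] - 2.5) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- ((-0.5 * t[i2] + 2.5) * t[i2] - 4) * t[i2] + 2
  w
}

#' Internuclear beam geometry
#'
#' Computes the anchors and line endpoints of the beam of `n` quasi-parallel
#' profiles spanning the axis between two neighbouring nuclei. For each
#' nucleus, the diameter perpendicular to the internuclear axis (the line
#' through the centroid, intersected with the nucleus boundary) provides two
#' anchor points, one on each side of the axis. Line `i` of the beam runs
#' parallel to the axis, from the point a fraction `i/(n-1)` along nucleus
#' A's perpendicular diameter to the point at the same fraction along B's,
#' `i = 0 ... n-1` — so the lines sweep the band between the two nuclei and
#' every one of them crosses the shared cell-cell interface near its
#' midpoint. Anchors on matching sides of the axis are paired, keeping the
#' lines quasi-parallel. If a perpendicular fails to hit the boundary the
#' anchors fall back to centroid +/- mean boundary radius (flagged).
#'
#' @param boundary_A,boundary_B closed boundary chains (`k x 2`, 0-based
#'   `(row, col)`), e.g. from [segment_nuclei()].
#' @param centroid_A,centroid_B nucleus centroids, `(row, col)`.
#' @param n number of lines in the beam (default 10).
#' @return list with `chord_A`, `chord_B` (2 x 2 matrices: the two diameter
#'   endpoints of each nucleus, matching sides in matching rows), `starts`
#'   and `ends` (`n x 2` matrices: line `i` runs `starts[i, ] -> ends[i, ]`),
#'   `m` (native profile length: the centroid distance, rounded, at least
#'   2), `fallback` flag.
#' @export
in_beam_endpoints <- function(boundary_A, boundary_B,
                              centroid_A, centroid_B, n = 10) {
  centroid_A <- as.numeric(centroid_A); centroid_B <- as.numeric(centroid_B)
  d <- centroid_B - centroid_A
  len <- sqrt(sum(d^2))
  if (len < .Machine$double.eps) stop("coincident nucleus centroids")
  u <- d / len
  v <- c(-u[2], u[1])  # perpendicular to the IN axis
  aA <- chord_anchor(boundary_A, centroid_A, v)
  aB <- chord_anchor(boundary_B, centroid_B, v)
  i <- (0:(n - 1)) / (n - 1)
  starts <- outer(rep(1, n), aA$pos) + outer(i, aA$neg - aA$pos)
  ends <- outer(rep(1, n), aB$pos) + outer(i, aB$neg - aB$pos)
  list(chord_A = rbind(aA$pos, aA$neg), chord_B = rbind(aB$pos, aB$neg),
       starts = starts, ends = ends,
       m = max(2L, as.integer(round(len))),
       fallback = aA$fallback || aB$fallback)
}

# intersect the line {center + t * v} with a closed boundary chain; return
# the nearest crossing on each side of the center (fallback: mean radius)
chord_anchor <- function(boundary, center, v) {
  boundary <- as.matrix(boundary)
  k <- nrow(boundary)
  p1 <- boundary
  p2 <- boundary[c(2:k, 1), , drop = FALSE]
  t_pos <- Inf; t_neg <- -Inf
  for (s in seq_len(k)) {
    hit <- seg_line_intersect(center, v, p1[s, ], p2[s, ])
    if (!is.na(hit)) {
      if (hit > 1e-9 && hit < t_pos) t_pos <- hit
      if (hit < -1e-9 && hit > t_neg) t_neg <- hit
    }
  }
  fallback <- FALSE
  if (!is.finite(t_pos) || !is.finite(t_neg)) {
    rad <- mean(sqrt(rowSums(sweep(boundary, 2, center)^2)))
    if (!is.finite(t_pos)) t_pos <- rad
    if (!is.finite(t_neg)) t_neg <- -rad
    fallback <- TRUE
  }
  list(pos = center + t_pos * v, neg = center + t_neg * v,
       fallback = fallback)
}

# parameter t of center + t*v crossing segment p1-p2 (NA when parallel or
# crossing outside the segment): solve t*v - s*e = p1 - center
seg_line_intersect <- function(center, v, p1, p2) {
  e <- p2 - p1
  det <- e[1] * v[2] - e[2] * v[1]
  if (abs(det) < 1e-12) return(NA_real_)
  rhs <- p1 - center
  t <- (e[1] * rhs[2] - e[2] * rhs[1]) / det
  s <- (v[1] * rhs[2] - v[2] * rhs[1]) / det
  if (s < -1e-9 || s > 1 + 1e-9) return(NA_real_)
  t
}

#' Sample an intensity profile along a segment
#'
#' Evaluates the image at `n_samples` evenly spaced sub-pixel positions
#' \eqn{p(j) = \mathrm{start} + \frac{j}{n-1}(\mathrm{end} -
#' \mathrm{start})} by bicubic interpolation. Positions outside the frame
#' are clamped to the border and the result carries a `clipped` attribute.
#'
#' @param image numeric matrix.
#' @param start,end `(row, col)` endpoints (0-based).
#' @param n_samples number of samples (>= 2).
#' @return numeric intensity vector with attribute `clipped`.
#' @export
sample_profile <- function(image, start, end, n_samples) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (sqrt(sum((end - start)^2)) < .Machine$double.eps)
    stop("degenerate profile: start equals end")
  stopifnot(n_samples >= 2)
  j <- (0:(n_samples - 1)) / (n_samples - 1)
  pts <- cbind(start[1] + j * (end[1] - start[1]),
               start[2] + j * (end[2] - start[2]))
  clipped <- any(pts[, 1] < 0 | pts[, 1] > nrow(image) - 1 |
                 pts[, 2] < 0 | pts[, 2] > ncol(image) - 1)
  out <- bicubic_sample(image, pts)
  if (all(image >= 0)) out <- pmax(out, 0)  # clip bicubic undershoot
  attr(out, "clipped") <- clipped
  out
}

#' Closed neighbourhood spline of a cell
#'
#' Periodic cubic spline through the centroids of a cell's network
#' neighbours, sorted by angle around the cell centre and parameterized by
#' cumulative chord length; returned densely sampled as a closed polyline.
#' This curve bounds the radial profiles of the cell. Cells with fewer than
#' three neighbours (image-border cells) cannot form a closed neighbourhood
#' and raise an error — callers exclude them from radial analysis.
#'
#' @param center cell centroid `(row, col)`.
#' @param neighbors `k x 2` matrix of neighbour centroids (`k >= 3`).
#' @param n_out number of polyline vertices (default 1024).
#' @return `n_out x 2` closed polyline (last vertex joins the first).
#' @export
rd_boundary_spline <- function(center, neighbors, n_out = 1024) {
  neighbors <- as.matrix(neighbors)
  if (nrow(neighbors) < 3)
    stop("radial boundary needs >= 3 neighbours (border cell excluded)")
  ang <- atan2(neighbors[, 1] - center[1], neighbors[, 2] - center[2])
  ord <- order(ang)
  pts <- neighbors[ord, , drop = FALSE]
  pts <- rbind(pts, pts[1, ])  # close the loop
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tout <- seq(0, tt[length(tt)], length.out = n_out + 1)[-(n_out + 1)]
  cbind(stats::spline(tt, pts[, 1], xout = tout, method = "periodic")$y,
        stats::spline(tt, pts[, 2], xout = tout, method = "periodic")$y)
}

#' Radial profile fan of a cell
#'
#' Casts `m` equi-spaced angular rays from the cell centroid; each ray ends
#' at its first intersection with the closed neighbourhood spline (ties
#' resolved to the smallest radius), giving native length
#' `r_i = round(distance)`, and intensities are sampled bicubically along
#' the ray. A centroid lying outside its own spline (no crossing) raises an
#' error and the cell is excluded upstream.
#'
#' @param image numeric matrix.
#' @param center cell centroid `(row, col)`.
#' @param spline closed polyline from [rd_boundary_spline()].
#' @param m number of rays (default 36).
#' @return list of class `"rd_fan"`: `profiles` (list of `m` intensity
#'   vectors), `lengths` (`r_i`), `angles`, `terminals` (`m x 2`).
#' @export
rd_profiles <- function(image, center, spline, m = 36) {
  stopifnot(m >= 1)
  angles <- 2 * pi * (0:(m - 1)) / m
  k <- nrow(spline)
  p1 <- spline
  p2 <- spline[c(2:k, 1), , drop = FALSE]
  profs <- vector("list", m)
  lens <- integer(m)
  terms <- matrix(NA_real_, m, 2)
  for (i in seq_len(m)) {
    dir <- c(sin(angles[i]), cos(angles[i]))
    t_min <- Inf
    for (s in seq_len(k)) {
      t <- seg_line_intersect(center, dir, p1[s, ], p2[s, ])
      if (!is.na(t) && t > 1e-9 && t < t_min) t_min <- t
    }
    if (!is.finite(t_min))
      stop("ray ", i, " does not intersect the boundary spline; ",
           "cell excluded from radial analysis")
    r_i <- max(2L, as.integer(round(t_min)))
    y_i <- center + t_min * dir
    profs[[i]] <- sample_profile(image, center, y_i, r_i)
    lens[i] <- r_i
    terms[i, ] <- y_i
  }
  structure(list(profiles = profs, lengths = lens, angles = angles,
                 terminals = terms, center = center),
            class = "rd_fan")
}

#' Normalize a profile to a fixed length
#'
#' Cubic-spline resampling of a native-length profile onto `N` evenly spaced
#' positions spanning its full extent; interior values are interpolated and
#' the endpoints are preserved exactly. Spline ringing is limited: output
#' values are clamped to the native range expanded by 5%, so resampling can
#' never invent extremes far outside the measured intensities.
#'
#' @param profile numeric vector (length >= 2).
#' @param N output length.
#' @return numeric vector of length `N`.
#' @export
normalize_length <- function(profile, N = 101) {
  m <- length(profile)
  if (m < 2) stop("profile too short to normalize (need >= 2 samples)")
  if (m == N) return(as.numeric(profile))
  if (m == 2) {
    return(stats::approx(c(0, 1), profile,
                         xout = seq(0, 1, length.out = N))$y)
  }
  out <- stats::spline(seq(0, 1, length.out = m), profile,
                       xout = seq(0, 1, length.out = N), method = "fmm")$y
  pad <- 0.05 * diff(range(profile))
  pmin(pmax(out, min(profile) - pad), max(profile) + pad)
}

#' Assemble length-normalized profiles into a profile matrix
#'
#' Stacks profiles as columns of an `N x M` matrix after length
#' normalization. All profiles must be of one kind (`"in"` or `"rd"`);
#' provenance (source pair / cell and member index) and native lengths ride
#' along as attributes.
#'
#' @param profiles list of numeric vectors (native lengths >= 2).
#' @param N normalized length (default 101 samples: positions 0-100, the
#'   internuclear midpoint at position 50).
#' @param kind `"in"` or `"rd"`.
#' @param provenance optional data frame with one row per profile.
#' @return `N x M` matrix of class `"profile_matrix"` with attributes
#'   `kind`, `provenance`, `native_lengths`.
#' @export
assemble_matrix <- function(profiles, N = 101, kind = c("in", "rd"),
                            provenance = NULL) {
  kind <- match.arg(kind)
  if (length(profiles) == 0) stop("no profiles to assemble")
  kinds <- unlist(lapply(profiles, function(p) attr(p, "kind") %||% kind))
  if (length(unique(kinds)) > 1)
    stop("cannot mix profile kinds in one matrix")
  native <- vapply(profiles, length, integer(1))
  Y <- vapply(profiles, normalize_length, numeric(N), N = N)
  if (all(unlist(profiles) >= 0)) Y <- pmax(Y, 0)  # clip spline undershoot
  structure(Y, kind = kind,
            provenance = provenance,
            native_lengths = native,
            class = c("profile_matrix", class(Y)))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile matrix: %d samples x %d %s profiles\n",
              nrow(x), ncol(x), toupper(attr(x, "kind"))))
  invisible(x)
}

#' Extract all internuclear beam profiles of a network
#'
#' For every network edge, computes the beam geometry with
#' [in_beam_endpoints()], samples the `n` lines at the native length (the
#' centroid distance) and assembles the length-normalized `N x (n * pairs)`
#' profile matrix.
#'
#' @param image marker-channel matrix.
#' @param network a `"cell_network"`.
#' @param nuclei a `"nucleus_set"` (boundaries for the chord anchors).
#' @param n lines per beam (default 10).
#' @param N normalized profile length (default 101).
#' @return a `"profile_matrix"` of kind `"in"`.
#' @export
extract_in_profiles <- function(image, network, nuclei, n = 10, N = 101) {
  edges <- network$edges
  if (nrow(edges) == 0) stop("network has no edges")
  profs <- list()
  prov <- data.frame(pair_a = integer(), pair_b = integer(),
                     line = integer())
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    beam <- in_beam_endpoints(nuclei$boundaries[[a]], nuclei$boundaries[[b]],
                              network$nodes[a, ], network$nodes[b, ], n)
    for (i in seq_len(n)) {
      profs[[length(profs) + 1]] <-
        sample_profile(image, beam$starts[i, ], beam$ends[i, ], beam$m)
      prov[nrow(prov) + 1, ] <- list(a, b, i - 1L)
    }
  }
  assemble_matrix(profs, N, "in", prov)
}

#' Extract all radial profile fans of a network
#'
#' For every cell with at least three network neighbours, builds the closed
#' neighbourhood spline, casts `m` equi-angular rays and assembles the
#' length-normalized radial profile matrix. Border cells (fewer than three
#' neighbours) and cells whose centroid lies outside their spline are
#' excluded and listed in the `excluded` attribute.
#'
#' @inheritParams extract_in_profiles
#' @param m rays per cell (default 36).
#' @return a `"profile_matrix"` of kind `"rd"` with attribute `excluded`.
#' @export
extract_rd_profiles <- function(image, network, m = 36, N = 101) {
  profs <- list()
  prov <- data.frame(cell = integer(), ray = integer())
  excluded <- data.frame(cell = integer(), reason = character())
  for (k in seq_len(nrow(network$nodes))) {
    nb <- network_neighbors(network, k)
    if (length(nb) < 3) {
      excluded[nrow(excluded) + 1, ] <- list(k, "fewer than 3 neighbours")
      next
    }
    fan <- tryCatch({
      sp <- rd_boundary_spline(network$nodes[k, ],
                               network$nodes[nb, , drop = FALSE])
      rd_profiles(image, network$nodes[k, ], sp, m)
    }, error = function(e) e)
    if (inherits(fan, "error")) {
      excluded[nrow(excluded) + 1, ] <- list(k, conditionMessage(fan))
      next
    }
    for (i in seq_len(m)) {
      profs[[length(profs) + 1]] <- fan$profiles[[i]]
      prov[nrow(prov) + 1, ] <- list(k, i - 1L)
    }
  }
  if (length(profs) == 0) stop("no cell has a closed neighbourhood; ",
                               "no radial profiles extracted")
  out <- assemble_matrix(profs, N, "rd", prov)
  attr(out, "excluded") <- excluded
  out
}
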