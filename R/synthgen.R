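#' Configuration for synthetic cell-population images
#'
#' Describes a seeded synthetic 2-channel fluorescence image: a confluent
#' field of elliptical cells with elliptical nuclei, a marker channel with
#' one of three localization patterns, and optional Poisson noise. All
#' intensities are in arbitrary units on an 8-bit-like \[0, 255\] scale.
#'
#' @param image_height,image_width frame size in pixels.
#' @param n_cells number of cells (>= 2).
#' @param nucleus_axes_range `(min, max)` ellipse semi-axes of nuclei, px.
#' @param cell_axes_range `(min, max)` ellipse semi-axes of cells, px; must
#'   exceed the nucleus axes.
#' @param jitter centroid placement noise (px) around a regular grid.
#' @param marker_mode `"membrane"`, `"cytoplasm"` or `"organelle"`.
#' @param membrane_width width (px) of the membrane ring; the
#'   perinuclear-organelle annulus uses twice this width.
#' @param base_intensity,peak_intensity background and structure intensity
#'   in \[0, 255\] a.u.
#' @param poisson_noise add per-pixel Poisson noise after rendering.
#' @param seed integer seed; the same configuration and seed reproduce
#'   byte-identical images.
#' @return list of class `"population_config"`.
#' @export
population_config <- function(image_height = 512, image_width = 512,
                              n_cells = 30,
                              nucleus_axes_range = c(8, 14),
                              cell_axes_range = c(28, 48),
                              jitter = 8,
                              marker_mode = c("membrane", "cytoplasm",
                                              "organelle"),
                              membrane_width = 3,
                              base_intensity = 20, peak_intensity = 200,
                              poisson_noise = TRUE, seed = 1) {
  marker_mode <- match.arg(marker_mode)
  stopifnot(n_cells >= 2,
            length(nucleus_axes_range) == 2, length(cell_axes_range) == 2,
            nucleus_axes_range[1] <= nucleus_axes_range[2],
            cell_axes_range[1] <= cell_axes_range[2],
            max(nucleus_axes_range) < min(cell_axes_range),
            base_intensity >= 0, peak_intensity <= 255,
            base_intensity < peak_intensity,
            jitter >= 0, membrane_width >= 1)
  structure(list(image_height = image_height, image_width = image_width,
                 n_cells = n_cells,
                 nucleus_axes_range = nucleus_axes_range,
                 cell_axes_range = cell_axes_range,
                 jitter = jitter, marker_mode = marker_mode,
                 membrane_width = membrane_width,
                 base_intensity = base_intensity,
                 peak_intensity = peak_intensity,
                 poisson_noise = isTRUE(poisson_noise),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a synthetic cell population image
#'
#' Places `n_cells` elliptical nuclei on a jittered grid (bounded retries
#' enforce a minimum centroid separation), partitions the whole frame into
#' confluent cell regions by an elliptical-metric Voronoi rule (each pixel
#' joins the cell whose scaled ellipse distance is smallest, so cells tile
#' the field with no gaps), renders the nuclei channel and the marker
#' channel per `marker_mode`, and finally adds Poisson noise when requested.
#'
#' Coordinates in the returned ground truth are 0-based `(row, col)` with
#' pixel centers at integer positions.
#'
#' @param config a [population_config()].
#' @return list of class `"synthetic_sample"`: `nuclei_channel` and
#'   `marker_channel` (numeric matrices), `true_centroids` (`n x 2`, 0-based
#'   row/col), `nucleus_masks` (integer label matrix), `cell_regions`
#'   (integer label matrix), `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  H <- config$image_height; W <- config$image_width
  n <- config$n_cells

  cen <- place_centroids(H, W, n, config)

  theta <- stats::runif(n, 0, pi)
  nuc_ax <- cbind(stats::runif(n, config$nucleus_axes_range[1],
                               config$nucleus_axes_range[2]),
                  stats::runif(n, config$nucleus_axes_range[1],
                               config$nucleus_axes_range[2]))
  cell_ax <- cbind(stats::runif(n, config$cell_axes_range[1],
                                config$cell_axes_range[2]),
                   stats::runif(n, config$cell_axes_range[1],
                                config$cell_axes_range[2]))

  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)

  # confluent partition: pixel -> argmin_k of the cell-ellipse metric
  best <- matrix(Inf, H, W)
  regions <- matrix(0L, H, W)
  masks <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    dr <- rows - cen[k, 1]; dc <- cols - cen[k, 2]
    u <- dr * cos(theta[k]) + dc * sin(theta[k])
    v <- -dr * sin(theta[k]) + dc * cos(theta[k])
    dk <- sqrt((u / cell_ax[k, 1])^2 + (v / cell_ax[k, 2])^2)
    win <- dk < best
    best[win] <- dk[win]
    regions[win] <- k
    masks[(u / nuc_ax[k, 1])^2 + (v / nuc_ax[k, 2])^2 <= 1] <- k
  }

  nuclei <- matrix(config$base_intensity, H, W)
  nuclei[masks > 0] <- config$peak_intensity

  marker <- matrix(config$base_intensity, H, W)
  for (k in seq_len(n)) {
    patch <- render_marker(regions == k, masks == k, config$marker_mode,
                           config)
    sel <- regions == k
    marker[sel] <- patch[sel]
  }

  if (config$poisson_noise) {
    nuclei <- add_poisson_noise(nuclei, seed = config$seed * 2L + 1L)
    marker <- add_poisson_noise(marker, seed = config$seed * 2L + 2L)
  }

  structure(list(nuclei_channel = nuclei, marker_channel = marker,
                 true_centroids = cen, nucleus_masks = masks,
                 cell_regions = regions, config = config),
            class = "synthetic_sample")
}

# jittered-grid centroid placement with bounded retries; errors out when
# n_cells cannot fit the frame at the required separation
place_centroids <- function(H, W, n, config) {
  margin <- max(config$nucleus_axes_range) + 2
  minsep <- 2 * max(config$nucleus_axes_range) + 4
  g <- ceiling(sqrt(n))
  gr <- ceiling(n / g)
  step_r <- (H - 2 * margin) / gr
  step_c <- (W - 2 * margin) / g
  if (step_r < minsep * 0.5 || step_c < minsep * 0.5)
    stop("placement failure: n_cells too large for the frame")
  slots <- expand.grid(r = seq_len(gr), c = seq_len(g))
  slots <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  cen <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in 1:50) {
      cand <- c(margin + (slots$r[k] - 0.5) * step_r,
                margin + (slots$c[k] - 0.5) * step_c) +
        stats::runif(2, -config$jitter, config$jitter)
      cand <- pmin(pmax(cand, margin), c(H, W) - 1 - margin)
      if (k == 1 ||
          min(sqrt(rowSums(sweep(cen[seq_len(k - 1), , drop = FALSE],
                                 2, cand)^2))) >= minsep) {
        cen[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement failure: could not satisfy the minimum ",
                      "centroid separation after bounded retries")
  }
  colnames(cen) <- c("row", "col")
  cen
}

#' Render the marker pattern for one cell region
#'
#' Noiseless intensity patch for a single cell, by marker localization:
#' `"membrane"` peaks on the region boundary and decays to background within
#' `membrane_width` px; `"cytoplasm"` rises smoothly from the nucleus toward
#' (but excluding) the boundary, which stays at background; `"organelle"`
#' fills a compact perinuclear annulus (thickness `2 * membrane_width`) and
#' is low elsewhere. Frame edges count as region boundary.
#'
#' @param region logical matrix, the cell's pixels.
#' @param nucleus logical matrix, the cell's nucleus pixels.
#' @param mode marker mode string.
#' @param config a [population_config()] (intensity and width parameters).
#' @return numeric intensity matrix the size of the frame.
#' @export
render_marker <- function(region, nucleus, mode, config) {
  if (!any(region)) stop("empty cell region")
  mode <- match.arg(mode, c("membrane", "cytoplasm", "organelle"))
  base <- config$base_intensity; peak <- config$peak_intensity
  w <- config$membrane_width
  db <- dist_to_boundary(region)           # distance to region boundary
  out <- matrix(base, nrow(region), ncol(region))
  if (mode == "membrane") {
    ramp <- pmax(0, 1 - (db - 1) / w)      # 1 on boundary pixels (db == 1)
    out[region] <- base + (peak - base) * ramp[region]
  } else if (mode == "cytoplasm") {
    dn <- dist_outside(nucleus)            # distance from the nucleus
    s <- dn / (dn + db)
    s[!is.finite(s)] <- 0
    out[region] <- base + (peak - base) * s[region]
    out[region & (db <= 1)] <- base        # boundary itself stays low
    out[nucleus] <- base
  } else {
    dn <- dist_outside(nucleus)
    annulus <- region & !nucleus & dn <= 2 * w
    out[annulus] <- peak
  }
  out
}

# Euclidean distance of each in-region pixel to the region boundary
# (frame edges count as boundary); 0 outside the region.
dist_to_boundary <- function(region) {
  padded <- matrix(FALSE, nrow(region) + 2, ncol(region) + 2)
  padded[2:(nrow(region) + 1), 2:(ncol(region) + 1)] <- region
  d <- EBImage::distmap(EBImage::Image(padded * 1))
  as.matrix(d)[2:(nrow(region) + 1), 2:(ncol(region) + 1)]
}

# Euclidean distance to the given set (0 inside it)
dist_outside <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
}

#' Add Poisson shot noise to an image
#'
#' Replaces every pixel by a Poisson draw with mean equal to the clean
#' intensity, then clips to the \[0, 255\] intensity range — the standard
#' photon-counting noise model of fluorescence microscopy.
#'
#' @param image non-negative numeric matrix.
#' @param seed integer seed (same seed, same noise).
#' @return noisy matrix of the same size.
#' @export
add_poisson_noise <- function(image, seed = 1) {
  if (any(image < 0)) stop("Poisson noise requires non-negative intensities")
  set.seed(seed)
  out <- matrix(stats::rpois(length(image), as.vector(image)),
                nrow(image), ncol(image))
  out[out > 255] <- 255
  out
}

#' Simulate a stack of warped noisy profiles from a known template
#'
#' Draws `M` profile columns \eqn{y_j(i) = f(g_j(x_i)) + \mathrm{noise}},
#' where each \eqn{g_j} is a random monotone cubic warp of \[0, 1\] fixing
#' the endpoints, \eqn{g_j(x) = x + a_j x (1 - x)(x - b_j)} with the
#' amplitude shrunk until the derivative stays positive. This is exactly the
#' generative model [compensate()] inverts, and the package's reference for
#' variance-reduction and template-recovery checks.
#'
#' @param f vectorized template function on \[0, 1\] (non-negative for
#'   Poisson noise).
#' @param M number of profiles.
#' @param N samples per profile.
#' @param noise `"poisson"`, `"awgn"` or `"none"`.
#' @param sd Gaussian noise SD (AWGN only).
#' @param warp_amp warp-amplitude multiplier (1 = default heterogeneity).
#' @param seed integer seed.
#' @return list with `Y` (`N x M`), `x` (uniform grid), `f_true` (`f(x)`),
#'   `warps` (`M x 2` matrix of `a`, `b`), `clean` (noiseless `Y`).
#' @export
simulate_warped_stack <- function(f, M = 30, N = 101,
                                  noise = c("poisson", "awgn", "none"),
                                  sd = 5, warp_amp = 1, seed = 1) {
  noise <- match.arg(noise)
  set.seed(seed)
  x <- seq(0, 1, length.out = N)
  a <- stats::runif(M, -1.5, 1.5) * warp_amp
  b <- stats::runif(M, 0.3, 0.7)
  clean <- matrix(NA_real_, N, M)
  for (j in seq_len(M)) {
    repeat {
      g <- x + a[j] * x * (1 - x) * (x - b[j])
      if (all(diff(g) > 0)) break
      a[j] <- a[j] / 2
    }
    clean[, j] <- f(g)
  }
  Y <- switch(noise,
    none = clean,
    poisson = matrix(stats::rpois(N * M, pmax(as.vector(clean), 0)), N, M),
    awgn = clean + matrix(stats::rnorm(N * M, 0, sd), N, M))
  list(Y = Y, x = x, f_true = f(x), warps = cbind(a = a, b = b),
       clean = clean)
}
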