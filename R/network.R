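#' Contrast-stretch a nuclei channel
#'
#' Percentile-clipped linear rescale to the full \[0, 255\] range: values
#' below/above the clip quantiles saturate, everything in between maps
#' linearly. The mapping is monotone, so pixel ordering is preserved, and it
#' is invariant to a global intensity scale. A constant image is returned
#' unchanged with a warning.
#'
#' @param image 2-D numeric matrix.
#' @param probs lower/upper clip quantiles.
#' @return rescaled matrix in \[0, 255\].
#' @export
preprocess <- function(image, probs = c(0.01, 0.99)) {
  stopifnot(is.matrix(image))
  q <- stats::quantile(image, probs, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: preprocessing skipped")
    return(image)
  }
  out <- (pmin(pmax(image, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * 255
  out
}

#' Segment nuclei and compute their centroids
#'
#' Global Otsu threshold, connected-component labelling, minimum-area
#' filtering, then a Moore-Neighbour boundary trace (with Jacob's stopping
#' criterion: the trace ends when the start pixel is re-entered from the
#' original direction) and the geometric centre of each component.
#'
#' @param image preprocessed nuclei channel (numeric matrix).
#' @param min_area discard components below this pixel area (speck filter).
#' @param threshold optional manual threshold overriding Otsu.
#' @return list of class `"nucleus_set"`: `records` data frame
#'   (`label`, `row`, `col`, `area` — centroids 0-based sub-pixel),
#'   `boundaries` list of ordered 0-based `(row, col)` boundary chains,
#'   `labels` integer label matrix.
#' @export
segment_nuclei <- function(image, min_area = 30, threshold = NULL) {
  stopifnot(is.matrix(image))
  mx <- max(image)
  if (is.null(threshold)) {
    if (mx <= min(image)) stop("no nuclei found: constant image")
    threshold <- EBImage::otsu(EBImage::Image(image / mx),
                               range = c(0, 1)) * mx
  }
  mask <- image > threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  if (max(lab) == 0) stop("no nuclei found above the threshold")
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0) stop("no nuclei found: all components below min_area")
  records <- data.frame(label = integer(), row = numeric(), col = numeric(),
                        area = integer())
  boundaries <- list()
  out_lab <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) {
    k <- keep[i]
    px <- which(lab == k, arr.ind = TRUE)  # 1-based
    records[i, ] <- list(i, mean(px[, 1]) - 1, mean(px[, 2]) - 1, nrow(px))
    boundaries[[i]] <- moore_trace(lab == k)
    out_lab[lab == k] <- i
  }
  structure(list(records = records, boundaries = boundaries,
                 labels = out_lab, threshold = threshold),
            class = "nucleus_set")
}

# Moore-Neighbour boundary tracing of one connected component, with Jacob's
# stopping criterion. Returns an ordered 0-based (row, col) matrix.
moore_trace <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  # scan order: top-to-bottom, left-to-right
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  # Moore neighbourhood, clockwise starting W
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(mask) &&
    p[2] >= 1 && p[2] <= ncol(mask) && mask[p[1], p[2]]
  chain <- matrix(start, 1, 2)
  p <- start
  enter_dir <- 1L  # came from the west (backtrack direction index)
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 1:8) {
      d <- ((enter_dir - 1 + s - 1) %% 8) + 1
      q <- p + dirs[d, ]
      if (inside(q)) {
        if (all(q == start)) {
          if (is.na(first_dir)) {
            first_dir <- d
          } else if (d == first_dir || nrow(chain) > 4 * sum(mask)) {
            return(chain - 1)   # Jacob: start re-entered, same direction
          }
        }
        chain <- rbind(chain, q)
        # new backtrack: the neighbour checked just before q, rotated to
        # be expressed relative to q
        prev <- ((d - 2) %% 8) + 1
        back <- p + dirs[prev, ] - q
        enter_dir <- which(dirs[, 1] == back[1] & dirs[, 2] == back[2])
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) return(chain - 1)  # isolated pixel
  }
}

#' Delaunay triangulation of a point set
#'
#' Plain Bowyer-Watson incremental triangulation. Returns the triangle list
#' as row indices into `points`; collinear or too-small inputs yield zero
#' triangles with a degeneracy flag.
#'
#' @param points `n x 2` numeric matrix of `(row, col)` coordinates.
#' @return list with `triangles` (`t x 3` integer matrix, vertex-sorted) and
#'   `degenerate` flag.
#' @export
delaunay_triangulation <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) return(list(triangles = matrix(integer(), 0, 3),
                         degenerate = TRUE))
  x <- points[, 2]; y <- points[, 1]
  # super-triangle
  cx <- mean(range(x)); cy <- mean(range(y))
  # far enough out that the artificial vertices act as points at infinity
  r <- max(diff(range(x)), diff(range(y)), 1) * 1e4
  px <- c(x, cx - 2 * r, cx + 2 * r, cx)
  py <- c(y, cy - r, cy - r, cy + 2 * r)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  for (i in seq_len(n)) {
    bad <- which(vapply(seq_len(nrow(tris)), function(t)
      in_circumcircle(px[tris[t, ]], py[tris[t, ]], px[i], py[i]),
      logical(1)))
    if (length(bad) == 0) next   # duplicate/degenerate point
    # keep only the edge-connected cavity around the triangle containing
    # the point: a nearly-cocircular remote triangle must not be carved
    # out, or the re-triangulated cavity would leave holes
    cont <- bad[vapply(bad, function(t)
      point_in_triangle(px[tris[t, ]], py[tris[t, ]], px[i], py[i]),
      logical(1))]
    if (length(cont) > 0 && length(bad) > 1) {
      ekey <- function(t) {
        v <- tris[t, ]
        c(paste(min(v[1], v[2]), max(v[1], v[2])),
          paste(min(v[2], v[3]), max(v[2], v[3])),
          paste(min(v[1], v[3]), max(v[1], v[3])))
      }
      keys <- lapply(bad, ekey)
      names(keys) <- as.character(bad)
      cavity <- cont[1]
      repeat {
        front <- unlist(keys[as.character(cavity)])
        grow <- bad[vapply(bad, function(t)
          !(t %in% cavity) && any(keys[[as.character(t)]] %in% front),
          logical(1))]
        if (length(grow) == 0) break
        cavity <- c(cavity, grow)
      }
      bad <- sort(cavity)
    }
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
    }))
    tris <- tris[-bad, , drop = FALSE]
    key <- paste(edges[, 1], edges[, 2])
    poly <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- rbind(tris, cbind(poly, i))
  }
  keep <- apply(tris, 1, function(v) {
    if (any(v > n)) return(FALSE)
    # drop zero-area (collinear) triangles
    a <- abs((px[v[2]] - px[v[1]]) * (py[v[3]] - py[v[1]]) -
             (py[v[2]] - py[v[1]]) * (px[v[3]] - px[v[1]]))
    a > 1e-9 * max(1, max(abs(c(px[v], py[v]))))^2
  })
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) {
    return(list(triangles = matrix(integer(), 0, 3), degenerate = TRUE))
  }
  tris <- matrix(t(apply(tris, 1, sort)), ncol = 3)
  list(triangles = tris, degenerate = FALSE)
}

# inclusive barycentric point-in-triangle test
point_in_triangle <- function(tx, ty, qx, qy) {
  d <- (ty[2] - ty[3]) * (tx[1] - tx[3]) + (tx[3] - tx[2]) * (ty[1] - ty[3])
  if (abs(d) < 1e-12) return(FALSE)
  a <- ((ty[2] - ty[3]) * (qx - tx[3]) + (tx[3] - tx[2]) * (qy - ty[3])) / d
  b <- ((ty[3] - ty[1]) * (qx - tx[3]) + (tx[1] - tx[3]) * (qy - ty[3])) / d
  cc <- 1 - a - b
  a >= -1e-9 && b >= -1e-9 && cc >= -1e-9
}

# circumcircle containment via explicit circumcenter; on-circle points count
# as inside (inclusive), so cocircular configurations retriangulate cleanly
in_circumcircle <- function(tx, ty, qx, qy) {
  d <- 2 * ((tx[2] - tx[1]) * (ty[3] - ty[1]) -
            (ty[2] - ty[1]) * (tx[3] - tx[1]))
  if (abs(d) < 1e-12) return(FALSE)  # degenerate triangle
  s1 <- tx[2]^2 - tx[1]^2 + ty[2]^2 - ty[1]^2
  s2 <- tx[3]^2 - tx[1]^2 + ty[3]^2 - ty[1]^2
  ux <- (s1 * (ty[3] - ty[1]) - s2 * (ty[2] - ty[1])) / d
  uy <- (s2 * (tx[2] - tx[1]) - s1 * (tx[3] - tx[1])) / d
  r2 <- (tx[1] - ux)^2 + (ty[1] - uy)^2
  (qx - ux)^2 + (qy - uy)^2 <= r2 * (1 + 1e-9)
}

#' Prune highly obtuse / overlong triangles
#'
#' Flags triangulation outliers: per triangle, the largest internal angle
#' \eqn{\phi_k} and the longest edge \eqn{\vartheta_k} are computed; a
#' triangle is removed when \eqn{\phi_k > \mu_\phi + 3\sigma_\phi} or
#' \eqn{\vartheta_k > \mu_\vartheta + 5\sigma_\vartheta}, with the
#' statistics taken once over all triangles (single pass, no re-iteration).
#' A single triangle is always kept (the SD is undefined).
#'
#' @param points `n x 2` centroid matrix.
#' @param triangles `t x 3` integer matrix of vertex indices.
#' @return list with `kept`, `removed` (both `t x 3` matrices), `reason`
#'   (character per removed triangle), `phi`, `len` (per input triangle).
#' @export
prune_obtuse_triangles <- function(points, triangles) {
  points <- as.matrix(points)
  t_n <- nrow(triangles)
  if (t_n == 0) return(list(kept = triangles,
                            removed = triangles[0, , drop = FALSE],
                            reason = character(0),
                            phi = numeric(0), len = numeric(0)))
  phi <- numeric(t_n); len <- numeric(t_n)
  for (t in seq_len(t_n)) {
    v <- points[triangles[t, ], , drop = FALSE]
    e <- c(sqrt(sum((v[1, ] - v[2, ])^2)),
           sqrt(sum((v[2, ] - v[3, ])^2)),
           sqrt(sum((v[1, ] - v[3, ])^2)))
    len[t] <- max(e)
    # law of cosines; largest angle opposes the longest edge
    cosangs <- c((e[2]^2 + e[3]^2 - e[1]^2) / (2 * e[2] * e[3]),
                 (e[1]^2 + e[3]^2 - e[2]^2) / (2 * e[1] * e[3]),
                 (e[1]^2 + e[2]^2 - e[3]^2) / (2 * e[1] * e[2]))
    phi[t] <- max(acos(pmin(pmax(cosangs, -1), 1)))
  }
  if (t_n < 2) {
    return(list(kept = triangles, removed = triangles[0, , drop = FALSE],
                reason = character(0), phi = phi, len = len))
  }
  bad_phi <- phi > mean(phi) + 3 * stats::sd(phi)
  bad_len <- len > mean(len) + 5 * stats::sd(len)
  bad <- bad_phi | bad_len
  reason <- ifelse(bad_phi[bad] & bad_len[bad], "angle+length",
                   ifelse(bad_phi[bad], "angle", "length"))
  list(kept = triangles[!bad, , drop = FALSE],
       removed = triangles[bad, , drop = FALSE],
       reason = reason, phi = phi, len = len)
}

#' Build the pruned Delaunay cell network
#'
#' Delaunay triangulation of the nucleus centroids followed by
#' [prune_obtuse_triangles()]; the edge set is the union of the kept
#' triangles' edges. With exactly two nuclei the network is the single pair
#' edge; with collinear centroids it has zero triangles and a degeneracy
#' flag.
#'
#' @param centroids `n x 2` matrix of `(row, col)` nucleus centres, or a
#'   `"nucleus_set"` from [segment_nuclei()].
#' @param prune apply the obtuse-triangle pruning rule.
#' @return list of class `"cell_network"`: `nodes` (centroid matrix),
#'   `edges` (`e x 2`), `triangles` (`t x 3`), `removed_triangles`,
#'   `removal_reason`, `degenerate`.
#' @export
build_network <- function(centroids, prune = TRUE) {
  if (inherits(centroids, "nucleus_set"))
    centroids <- as.matrix(centroids$records[, c("row", "col")])
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("need at least 2 nuclei to build a network")
  if (n == 2) {
    return(structure(list(nodes = centroids,
                          edges = matrix(c(1L, 2L), 1, 2),
                          triangles = matrix(integer(), 0, 3),
                          removed_triangles = matrix(integer(), 0, 3),
                          removal_reason = character(0),
                          degenerate = FALSE),
                     class = "cell_network"))
  }
  dt <- delaunay_triangulation(centroids)
  pr <- if (prune) prune_obtuse_triangles(centroids, dt$triangles)
        else list(kept = dt$triangles,
                  removed = dt$triangles[0, , drop = FALSE],
                  reason = character(0))
  tri <- pr$kept
  edges <- unique(do.call(rbind, lapply(seq_len(nrow(tri)), function(t) {
    v <- tri[t, ]
    rbind(v[1:2], v[2:3], v[c(1, 3)])
  })))
  if (is.null(edges)) edges <- matrix(integer(), 0, 2)
  structure(list(nodes = centroids, edges = edges, triangles = tri,
                 removed_triangles = pr$removed,
                 removal_reason = pr$reason,
                 degenerate = dt$degenerate),
            class = "cell_network")
}

#' Neighbours of a node in a cell network
#'
#' @param network a `"cell_network"`.
#' @param k node index.
#' @return integer vector of neighbouring node indices.
#' @export
network_neighbors <- function(network, k) {
  e <- network$edges
  sort(unique(c(e[e[, 1] == k, 2], e[e[, 2] == k, 1])))
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("Cell network: %d nuclei, %d edges, %d triangles (%d pruned)%s\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$triangles),
              nrow(x$removed_triangles),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
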