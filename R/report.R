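#' Render a profile map as a heatmap PNG
#'
#' Rows are profile positions, columns are profiles; intensities are scaled
#' to the grey range. Returns the 0-1 grey matrix invisibly; writes a PNG
#' when `file` is given.
#'
#' @param map `N x M` numeric matrix.
#' @param file optional PNG path.
#' @return grey-level matrix, invisibly.
#' @export
render_map <- function(map, file = NULL) {
  map <- as.matrix(map)
  if (length(map) == 0) stop("empty map")
  rng <- range(map)
  g <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1])
       else matrix(0.5, nrow(map), ncol(map))
  if (!is.null(file)) png::writePNG(g, file)
  invisible(g)
}

#' Virtual cell pair from an internuclear ideal profile
#'
#' Renders the population-typical internuclear signal: two template nuclei
#' at a fixed distance, with every chord of the beam region between them
#' colored by the ideal profile evaluated at the normalized position along
#' the chord. Purely a visualization of `f`; geometry constants (nucleus
#' radius, pair distance) are fixed template values.
#'
#' @param f ideal profile: function on \[0, 1\], a coefficient vector, or a
#'   `"compensation"` fit.
#' @param size image side (px).
#' @param nucleus_radius,pair_distance template geometry (px).
#' @param file optional PNG path.
#' @return intensity matrix, invisibly.
#' @export
virtual_cell_pair <- function(f, size = 201, nucleus_radius = 30,
                              pair_distance = 120, file = NULL) {
  f <- as_profile_fun(f)
  mid <- (size - 1) / 2
  cA <- c(mid, mid - pair_distance / 2)
  cB <- c(mid, mid + pair_distance / 2)
  img <- matrix(0, size, size)
  rows <- matrix(0:(size - 1), size, size)
  cols <- matrix(0:(size - 1), size, size, byrow = TRUE)
  # beam region: between the chord lines through the two nuclei
  xpos <- (cols - cA[2]) / (cB[2] - cA[2])
  band <- xpos >= 0 & xpos <= 1 & abs(rows - mid) <= nucleus_radius
  img[band] <- f(xpos[band])
  for (cc in list(cA, cB)) {
    nuc <- (rows - cc[1])^2 + (cols - cc[2])^2 <= nucleus_radius^2
    img[nuc] <- max(img) * 0.25
  }
  if (!is.null(file)) render_map(img, file)
  invisible(img)
}

#' Polar virtual cell from a radial ideal profile
#'
#' Radially symmetric rendering: the pixel at normalized radius `r` from the
#' image centre is colored by `f(r)`; radii beyond 1 stay background.
#'
#' @inheritParams virtual_cell_pair
#' @param radius cell radius in px.
#' @return intensity matrix, invisibly.
#' @export
virtual_cell_polar <- function(f, size = 201, radius = 95, file = NULL) {
  f <- as_profile_fun(f)
  mid <- (size - 1) / 2
  rows <- matrix(0:(size - 1), size, size)
  cols <- matrix(0:(size - 1), size, size, byrow = TRUE)
  r <- sqrt((rows - mid)^2 + (cols - mid)^2) / radius
  img <- matrix(0, size, size)
  inside <- r <= 1
  img[inside] <- f(r[inside])
  if (!is.null(file)) render_map(img, file)
  invisible(img)
}

as_profile_fun <- function(f) {
  if (inherits(f, "compensation")) {
    cc <- f$c
    function(x) eval_profile(x, cc)
  } else if (is.numeric(f)) {
    cc <- f
    function(x) eval_profile(x, cc)
  } else if (is.function(f)) f
  else stop("cannot interpret the ideal profile argument")
}

#' Run the full profiling pipeline on an image pair
#'
#' Segmentation, network construction, profile extraction and geometric
#' compensation in one call: the composition a user runs per image. Errors
#' from any stage propagate with the stage name. When `out_dir` is given,
#' the summary JSON, curve CSVs and figure PNGs are written there.
#'
#' @param nuclei_channel,marker_channel numeric matrices (one image).
#' @param kind `"in"`, `"rd"` or `"both"`.
#' @param params an [alignment_params()]; symmetry is forced per kind
#'   (internuclear symmetric, radial not).
#' @param n,m,N extraction settings (lines per beam, rays per cell,
#'   normalized length).
#' @param min_area segmentation speck filter.
#' @param out_dir optional output directory.
#' @return list of class `"profile_report"` with per-kind entries
#'   (`fit`, `map`, `summary`, `profiles`) plus `network` and `nuclei`.
#' @export
run_pipeline <- function(nuclei_channel, marker_channel,
                         kind = c("in", "rd", "both"),
                         params = alignment_params(),
                         n = 10, m = 36, N = 101, min_area = 30,
                         out_dir = NULL) {
  kind <- match.arg(kind)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  nuclei <- stage("segmentation",
                  segment_nuclei(preprocess(nuclei_channel), min_area))
  network <- stage("network", build_network(nuclei))
  out <- list(network = network, nuclei = nuclei)
  kinds <- if (kind == "both") c("in", "rd") else kind
  for (kd in kinds) {
    pm <- stage(paste0(kd, "-extraction"),
                if (kd == "in")
                  extract_in_profiles(marker_channel, network, nuclei, n, N)
                else extract_rd_profiles(marker_channel, network, m, N))
    fit <- stage(paste0(kd, "-alignment"),
                 compensate(pm, params, symmetric = (kd == "in")))
    map <- compensated_map(fit)
    out[[kd]] <- list(profiles = pm, fit = fit, map = map,
                      summary = summarize_map(map, fit$omega))
  }
  class(out) <- "profile_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.profile_report <- function(x, ...) {
  cat("Profile report\n")
  print(x$network)
  for (kd in intersect(c("in", "rd"), names(x))) {
    s <- x[[kd]]$summary
    cat(sprintf("  %s: %d profiles, peak %.2f a.u. at position %d\n",
                toupper(kd), ncol(x[[kd]]$map), s$peak_value,
                s$peak_position))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list()
  for (kd in intersect(c("in", "rd"), names(report))) {
    s <- report[[kd]]$summary
    utils::write.csv(data.frame(position = s$position, mean = s$mean,
                                sd = s$sd),
                     file.path(out_dir, paste0(kd, "_curve.csv")),
                     row.names = FALSE)
    render_map(report[[kd]]$map, file.path(out_dir, paste0(kd, "_map.png")))
    fit <- report[[kd]]$fit
    if (kd == "in") virtual_cell_pair(fit,
                                      file = file.path(out_dir,
                                                       "virtual_pair.png"))
    else virtual_cell_polar(fit,
                            file = file.path(out_dir, "virtual_cell.png"))
    summ[[kd]] <- list(peak_position = s$peak_position,
                       peak_value = s$peak_value,
                       n_profiles_used = s$n_profiles_used,
                       outliers = sum(fit$omega == 0),
                       iterations = fit$iter,
                       converged = fit$converged)
  }
  summ$n_nuclei <- nrow(report$network$nodes)
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
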