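#' Write / read a profile matrix as CSV
#'
#' Plain-text container for profile stacks: columns are profiles, the header
#' row encodes kind, provenance and native length per column as
#' `kind:source:index:native_length`, so a matrix round-trips with its
#' metadata.
#'
#' @param pm a `"profile_matrix"`.
#' @param path CSV file path.
#' @export
write_profile_matrix <- function(pm, path) {
  kind <- attr(pm, "kind")
  prov <- attr(pm, "provenance")
  native <- attr(pm, "native_lengths")
  M <- ncol(pm)
  src <- if (!is.null(prov) && nrow(prov) == M) {
    if (kind == "in") paste0(prov$pair_a, "-", prov$pair_b, ":", prov$line)
    else paste0(prov$cell, ":", prov$ray)
  } else paste0("NA:", seq_len(M) - 1)
  header <- paste0(kind, ":", src, ":", native %||% rep(NA, M))
  df <- as.data.frame(unclass(pm))
  names(df) <- header
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @return `read_profile_matrix()` returns the `"profile_matrix"`.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  header <- names(df)
  parts <- strsplit(header, ":", fixed = TRUE)
  kind <- parts[[1]][1]
  native <- suppressWarnings(
    as.integer(vapply(parts, function(p) p[length(p)], character(1))))
  Y <- as.matrix(df)
  dimnames(Y) <- NULL
  src <- vapply(parts, function(p)
    paste(p[-c(1, length(p))], collapse = ":"), character(1))
  prov <- if (kind == "in") {
    ab <- strsplit(vapply(strsplit(src, ":"), `[`, character(1), 1), "-")
    data.frame(pair_a = as.integer(vapply(ab, `[`, character(1), 1)),
               pair_b = as.integer(vapply(ab, `[`, character(1), 2)),
               line = as.integer(vapply(strsplit(src, ":"), `[`,
                                        character(1), 2)))
  } else {
    sp <- strsplit(src, ":")
    data.frame(cell = suppressWarnings(
                 as.integer(vapply(sp, `[`, character(1), 1))),
               ray = suppressWarnings(
                 as.integer(vapply(sp, `[`, character(1), 2))))
  }
  structure(Y, kind = kind, provenance = prov, native_lengths = native,
            class = c("profile_matrix", class(Y)))
}

#' Write a synthetic sample to disk
#'
#' Channels and the nucleus label mask go to 16-bit TIFF, ground-truth
#' centroids and the configuration to JSON.
#'
#' @param sample a `"synthetic_sample"`.
#' @param dir output directory (created if needed).
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(sample$nuclei_channel / 255,
                  file.path(dir, "nuclei.tif"), bits.per.sample = 16)
  tiff::writeTIFF(sample$marker_channel / 255,
                  file.path(dir, "marker.tif"), bits.per.sample = 16)
  tiff::writeTIFF(sample$nucleus_masks / 65535,
                  file.path(dir, "nucleus_masks.tif"), bits.per.sample = 16)
  jsonlite::write_json(list(true_centroids = sample$true_centroids,
                            config = unclass(sample$config)),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a single-channel image (TIFF or PNG) as an intensity matrix
#'
#' Intensities are returned on the \[0, 255\] scale; multi-channel images
#' are reduced to their first channel.
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_channel <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}
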