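# Two-channel image quantification: mitochondrial enrichment ratio,
# punctum (ERMES-style) enrichment, and crop coefficient-of-variation
# heterogeneity. Images are plain numeric matrices with a pixel size in
# micrometres per pixel; masks are logical matrices of the same shape.

#' Create an image channel
#'
#' @param pixels 2-D numeric matrix of non-negative intensities.
#' @param pixel_size Pixel edge length in micrometres (> 0).
#' @return Object of class `image_channel`.
#' @export
image_channel <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_invalid("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_invalid("intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_invalid("pixel_size must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "image_channel")
}

#' @export
print.image_channel <- function(x, ...) {
  cat(sprintf("<image_channel> %d x %d px @ %.3f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Create a region mask
#'
#' @param mask Logical matrix.
#' @param kind One of `"mitochondria"`, `"cell"`, `"punctum"`.
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(mask, kind = c("mitochondria", "cell", "punctum")) {
  kind <- match.arg(kind)
  if (!is.matrix(mask) || !is.logical(mask))
    stop_invalid("mask must be a logical matrix")
  structure(list(mask = mask, kind = kind), class = "region_mask")
}

as_mask <- function(x) if (inherits(x, "region_mask")) x$mask else x

check_shapes <- function(channel, ...) {
  for (m in list(...)) {
    if (!identical(dim(channel$pixels), dim(m)))
      stop_invalid("mask shape does not match channel shape")
  }
}

#' Otsu threshold of an image
#'
#' Maximizes between-class variance over a 256-bin histogram of the intensity
#' range; used to turn a mitochondrial marker channel into a mask.
#'
#' @param pixels Numeric matrix.
#' @param n_bins Histogram bins (default 256).
#' @return Threshold value (pixels strictly above it are foreground).
#' @export
otsu_threshold <- function(pixels, n_bins = 256L) {
  v <- as.numeric(pixels)
  rng <- range(v)
  if (diff(rng) == 0)
    stop_invalid("constant image: automatic thresholding undefined, supply a manual threshold")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Threshold a marker channel into a region mask
#'
#' @param marker An [image_channel] (e.g. the mitochondrial marker).
#' @param method `"otsu"` or a single numeric manual threshold.
#' @param kind Mask kind label (default `"mitochondria"`).
#' @return A [region_mask]; pixels strictly above the threshold are TRUE.
#' @export
threshold_mask <- function(marker, method = "otsu", kind = "mitochondria") {
  stopifnot(inherits(marker, "image_channel"))
  thr <- if (is.numeric(method)) method else {
    if (!identical(method, "otsu")) stop_invalid("unknown threshold method")
    otsu_threshold(marker$pixels)
  }
  m <- region_mask(marker$pixels > thr, kind)
  attr(m, "threshold") <- thr
  m
}

enrichment_result <- function(statistic, value, on_region, off_region) {
  structure(list(statistic = statistic, value = value,
                 on_region = on_region, off_region = off_region),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<%s> value = %.4f (on: %.4g, off: %.4g)\n",
              x$statistic, x$value, x$on_region, x$off_region))
  invisible(x)
}

#' Mitochondrial enrichment ratio
#'
#' Mean client fluorescence over the mitochondrial mask divided by the mean
#' client fluorescence over the rest of the cell (cell mask minus
#' mitochondrial mask). A value of 1 means no enrichment.
#'
#' @param client Client [image_channel] (the protein being scored).
#' @param mito_mask Mitochondrial [region_mask] — derived from the marker
#'   channel, never from the client channel.
#' @param cell_mask Cell [region_mask]; must contain the mitochondrial mask.
#' @return An `enrichment_result` with `value` = on/off mean ratio.
#' @export
mito_enrichment_ratio <- function(client, mito_mask, cell_mask) {
  stopifnot(inherits(client, "image_channel"))
  mito <- as_mask(mito_mask); cell <- as_mask(cell_mask)
  check_shapes(client, mito, cell)
  if (any(mito & !cell))
    stop_invalid("mitochondrial mask must lie within the cell mask")
  off <- cell & !mito
  if (!any(mito)) stop_invalid("empty mitochondrial mask")
  if (!any(off)) stop_invalid("empty off-mitochondria region (cell minus mitochondria)")
  on_mean <- mean(client$pixels[mito])
  off_mean <- mean(client$pixels[off])
  if (off_mean <= 0) stop_invalid("off-region mean is zero: ratio undefined")
  enrichment_result("mito_enrichment_ratio", on_mean / off_mean,
                    on_mean, off_mean)
}

#' Punctum (integrated-density) enrichment
#'
#' Integrated client density over the punctum mask divided by the integrated
#' density over the whole cell; lies in `[0, 1]` and equals the punctum area
#' fraction for spatially uniform signal.
#'
#' @param signal Signal [image_channel].
#' @param punctum_mask Punctum [region_mask] (e.g. ERMES foci).
#' @param cell_mask Whole-cell [region_mask]; must contain the punctum mask.
#' @return An `enrichment_result` with `value` in `[0, 1]`.
#' @export
punctum_enrichment <- function(signal, punctum_mask, cell_mask) {
  stopifnot(inherits(signal, "image_channel"))
  punc <- as_mask(punctum_mask); cell <- as_mask(cell_mask)
  check_shapes(signal, punc, cell)
  if (any(punc & !cell)) stop_invalid("punctum mask must lie within the cell mask")
  total <- sum(signal$pixels[cell])
  if (total <= 0) stop_invalid("zero whole-cell integrated density")
  on <- sum(signal$pixels[punc])
  enrichment_result("punctum_enrichment", on / total, on, total)
}

#' Coefficient-of-variation heterogeneity of a square crop
#'
#' Population standard deviation divided by mean intensity over a square crop
#' of fixed physical area (default 8 um^2, the crop size used for recruitment
#' heterogeneity scoring). The crop side is `floor(sqrt(area)/pixel_size)`
#' pixels, minimum 2; scale-invariant in the intensities.
#'
#' @param client Client [image_channel].
#' @param crop_center Length-2 integer vector `(row, col)` of the crop centre
#'   in pixels.
#' @param crop_area Crop area in um^2 (default 8).
#' @return An `enrichment_result` with `value` = CoV; the crop bounds are
#'   attached as attribute `crop`.
#' @export
crop_cov_heterogeneity <- function(client, crop_center, crop_area = 8) {
  stopifnot(inherits(client, "image_channel"))
  side <- max(2L, floor(sqrt(crop_area) / client$pixel_size))
  half <- side %/% 2L
  r0 <- crop_center[1L] - half; c0 <- crop_center[2L] - half
  r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(client$pixels) || c1 > ncol(client$pixels))
    stop_invalid("crop (%d px square at %d,%d) falls outside the image",
                 side, crop_center[1L], crop_center[2L])
  crop <- client$pixels[r0:r1, c0:c1]
  m <- mean(crop)
  if (m <= 0) stop_invalid("zero mean intensity in crop: CoV undefined")
  pop_sd <- sqrt(mean((crop - m)^2))
  out <- enrichment_result("crop_cov_heterogeneity", pop_sd / m, pop_sd, m)
  attr(out, "crop") <- c(row0 = r0, row1 = r1, col0 = c0, col1 = c1)
  out
}

#' Read / write an image channel as TSV text
#'
#' Plain-text exchange format (no TIFF reader is available in this
#' environment): tab-separated pixel matrix with a `# pixel_size=` header.
#' @param path File path.
#' @param channel An [image_channel] (for writing).
#' @return [image_channel] (read) or `path` invisibly (write).
#' @export
read_channel_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  ps <- as.numeric(sub("^#\\s*pixel_size=", "", first))
  m <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(m) <- NULL
  image_channel(m, ps)
}

#' @rdname read_channel_tsv
#' @export
write_channel_tsv <- function(channel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size=%.6g", channel$pixel_size), con)
  utils::write.table(channel$pixels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
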