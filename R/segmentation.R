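# Tongue extraction and the extended ratio-based (Chiu-style) partition
# into edge / posterior / middle / apex, plus region color summaries.
#
# Orientation convention: images are upright with the tongue root at the top
# and the apex at the bottom; matrices are row-major with origin top-left.

REGION_LEVELS <- c("background", "edge", "posterior", "middle", "apex")

#' Construct a tongue image
#'
#' Wraps an RGB raster (as returned by [read_tongue_image()] or built in
#' code) together with its acquisition metadata.
#'
#' @param rgb A height x width x 3 numeric array, channels in `[0, 1]`.
#' @param subject_id Subject identifier.
#' @param position `"sitting"` or `"supine"`.
#' @param seconds_after_change Optional seconds since the position change
#'   (tongues are photographed within about 3 minutes of assuming the
#'   supine position).
#' @return A `"tongue_image"` object.
#' @export
tongue_image <- function(rgb, subject_id = NA_character_,
                         position = c("sitting", "supine"),
                         seconds_after_change = NA_real_) {
  position <- match.arg(position)
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("rgb must be a height x width x 3 array", call. = FALSE)
  if (any(dim(rgb)[1:2] < 1L)) stop("image must be at least 1 x 1", call. = FALSE)
  structure(
    list(rgb = rgb,
         meta = list(subject_id = subject_id, position = position,
                     seconds_after_change = seconds_after_change)),
    class = "tongue_image")
}

#' Read a tongue photograph from PNG or TIFF
#'
#' 8-bit or 16-bit channels are scaled to `[0, 1]` on read; an alpha channel,
#' if present, is dropped.
#'
#' @inheritParams tongue_image
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `"tongue_image"` object.
#' @export
read_tongue_image <- function(path, subject_id = NA_character_,
                              position = "sitting",
                              seconds_after_change = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  tongue_image(raw, subject_id, position, seconds_after_change)
}

# flatten an RGB array to an n x 3 matrix of pixels (row-major pairing kept
# consistent by using the array's natural column-major order everywhere)
.pixels_of <- function(rgb) {
  matrix(rgb, ncol = 3L)
}

#' Segment the tongue from an image
#'
#' The tongue is identified by redness dominance: each pixel is converted to
#' L*a*b* and pixels with `a* > a_threshold` (and `L* > min_L`, to exclude
#' near-black noise) form the candidate foreground. The largest connected
#' component is kept and its holes filled, giving a single connected mask.
#' The procedure is deterministic for a fixed image and configuration.
#'
#' @param image A `"tongue_image"`.
#' @param a_threshold Minimum chromatic `a*` (redness) for a tongue pixel;
#'   default 12 sits well below typical tongue redness (`a*` 20-35) and well
#'   above neutral backgrounds (`a*` near 0).
#' @param min_L Minimum lightness for a tongue pixel.
#' @param white_point Passed to [rgb_to_lab()].
#' @return A `"tongue_mask"`: a logical height x width matrix, `TRUE` on the
#'   tongue.
#' @export
segment_tongue <- function(image, a_threshold = 12, min_L = 5,
                           white_point = "D65") {
  stopifnot(inherits(image, "tongue_image"))
  lab <- rgb_to_lab(.pixels_of(image$rgb), white_point = white_point)
  fg <- lab[, "a"] > a_threshold & lab[, "L"] > min_L
  dims <- dim(image$rgb)[1:2]
  fg <- matrix(fg, nrow = dims[1L], ncol = dims[2L])
  if (!any(fg)) stop("no tongue found: no pixel passes the redness criterion",
                     call. = FALSE)
  comp <- EBImage::bwlabel(fg)
  sizes <- tabulate(comp[comp > 0])
  keep <- which.max(sizes)
  mask <- comp == keep
  mask <- EBImage::fillHull(mask) > 0
  structure(mask, class = c("tongue_mask", class(mask)))
}

#' Partition ratios for the extended Chiu-style scheme
#'
#' The partition ratios are deliberately explicit configuration: the
#' ratio-based tongue partition is defined only diagrammatically in the
#' literature, so the defaults here are documented provisional values and
#' every downstream report carries the ratios actually used.
#'
#' @param edge Fraction of each row's tongue width assigned to the lateral
#'   edge band on *each* side (so a row keeps `1 - 2 * edge` of its width as
#'   middle).
#' @param posterior Fraction of the mask bounding-box height, from the top,
#'   forming the posterior region.
#' @param apex Fraction from the bottom forming the apex region.
#' @return A named list of class `"partition_ratios"`.
#' @export
partition_ratios <- function(edge = 0.15, posterior = 0.20, apex = 0.20) {
  if (any(c(edge, posterior, apex) <= 0) || any(c(edge, posterior, apex) >= 1))
    stop("all partition ratios must lie in (0, 1)", call. = FALSE)
  if (posterior + apex >= 1)
    stop("posterior + apex fractions must be < 1", call. = FALSE)
  if (2 * edge >= 1)
    stop("edge fraction must be < 0.5 of the row width", call. = FALSE)
  structure(list(edge = edge, posterior = posterior, apex = apex),
            class = "partition_ratios")
}

#' Partition a tongue mask into edge, posterior, middle and apex
#'
#' Extends the classic three-region ratio partition (edge / middle / top)
#' with a posterior region, giving the four regions used in tongue
#' diagnosis. Within the mask's bounding box, the top `posterior` fraction
#' of rows is the posterior region and the bottom `apex` fraction the apex;
#' in each remaining row the outermost `edge` fraction of that row's tongue
#' pixels on each side is edge, the rest middle. The bands follow each row's
#' own tongue run, so the edge band tracks the tongue outline rather than
#' the bounding box. The four regions partition the mask exactly.
#'
#' @param mask A `"tongue_mask"` or logical matrix with at least one `TRUE`.
#' @param ratios A [partition_ratios()] object.
#' @return A `"region_partition"`: list with `labels` (integer matrix, 0 =
#'   background, 1 = edge, 2 = posterior, 3 = middle, 4 = apex), `levels`,
#'   and the `ratios` used.
#' @export
partition_regions <- function(mask, ratios = partition_ratios()) {
  if (!is.matrix(mask) || !is.logical(c(mask[1L])))
    mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("degenerate partition: empty mask", call. = FALSE)
  stopifnot(inherits(ratios, "partition_ratios"))

  rows_with <- which(rowSums(mask) > 0)
  r0 <- min(rows_with); r1 <- max(rows_with)
  H <- r1 - r0 + 1L
  n_post <- round(ratios$posterior * H)
  n_apex <- round(ratios$apex * H)

  labels <- matrix(0L, nrow(mask), ncol(mask))
  post_rows <- if (n_post > 0) r0:(r0 + n_post - 1L) else integer(0)
  apex_rows <- if (n_apex > 0) (r1 - n_apex + 1L):r1 else integer(0)
  labels[post_rows, ][mask[post_rows, , drop = FALSE]] <- 2L
  labels[apex_rows, ][mask[apex_rows, , drop = FALSE]] <- 4L

  mid_rows <- setdiff(r0:r1, c(post_rows, apex_rows))
  for (r in mid_rows) {
    cols <- which(mask[r, ])
    n <- length(cols)
    if (n == 0L) next
    n_edge <- min(round(ratios$edge * n), n %/% 2L)
    lab_row <- rep(3L, n)
    if (n_edge > 0) {
      lab_row[seq_len(n_edge)] <- 1L
      lab_row[(n - n_edge + 1L):n] <- 1L
    }
    labels[r, cols] <- lab_row
  }

  counts <- tabulate(labels[labels > 0L], nbins = 4L)
  if (any(counts == 0L))
    stop("degenerate partition: mask too small to populate all four regions",
         call. = FALSE)
  structure(list(labels = labels, levels = REGION_LEVELS, ratios = ratios),
            class = "region_partition")
}

.region_code <- function(region) {
  code <- match(region, REGION_LEVELS[-1L])
  if (is.na(code)) stop("unknown region: ", region, call. = FALSE)
  code
}

#' Pixel count per region
#' @param partition A `"region_partition"`.
#' @return Named integer vector over edge, posterior, middle, apex.
#' @export
region_sizes <- function(partition) {
  stopifnot(inherits(partition, "region_partition"))
  counts <- tabulate(partition$labels[partition$labels > 0L], nbins = 4L)
  names(counts) <- REGION_LEVELS[-1L]
  counts
}

#' Mean L*a*b* color of a tongue region
#'
#' Converts every pixel of the requested region to L*a*b* and returns the
#' arithmetic channel-wise mean. The edge region, least affected by tongue
#' coating, is the one used in the positional color analysis.
#'
#' @param image The `"tongue_image"` the partition was computed on.
#' @param partition A `"region_partition"` with the same spatial dimensions.
#' @param region One of `"edge"`, `"posterior"`, `"middle"`, `"apex"`.
#' @param stat `"mean"` (default) or `"median"` (channel-wise).
#' @param white_point Passed to [rgb_to_lab()].
#' @return A 1 x 3 matrix `(L, a, b)`.
#' @export
region_mean_lab <- function(image, partition, region = "edge",
                            stat = c("mean", "median"), white_point = "D65") {
  stopifnot(inherits(image, "tongue_image"),
            inherits(partition, "region_partition"))
  stat <- match.arg(stat)
  if (!all(dim(partition$labels) == dim(image$rgb)[1:2]))
    stop("partition and image dimensions differ", call. = FALSE)
  sel <- partition$labels == .region_code(region)
  if (!any(sel)) stop("region '", region, "' is empty", call. = FALSE)
  px <- .pixels_of(image$rgb)[c(sel), , drop = FALSE]
  lab <- rgb_to_lab(px, white_point = white_point)
  fun <- if (stat == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  matrix(fun(lab), nrow = 1L, dimnames = list(NULL, c("L", "a", "b")))
}

#' Mean L*a*b* of every region at once
#'
#' @inheritParams region_mean_lab
#' @return Named list of 1 x 3 matrices over the four regions.
#' @export
all_region_means <- function(image, partition, stat = "mean",
                             white_point = "D65") {
  regs <- REGION_LEVELS[-1L]
  stats::setNames(
    lapply(regs, function(r)
      region_mean_lab(image, partition, r, stat = stat,
                      white_point = white_point)),
    regs)
}

#' Jaccard overlap between two masks
#' @param a,b Logical matrices of equal dimension.
#' @return Intersection over union, in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  sum(a & b) / sum(a | b)
}

#' Write a region partition as a label PNG
#'
#' Labels 0 (background) to 4 (apex) are scaled into the 8-bit gray range
#' `label / 4` so standard viewers show the partition; [read_label_png()]
#' inverts the scaling.
#'
#' @param partition A `"region_partition"`.
#' @param path Output PNG path.
#' @export
write_label_png <- function(partition, path) {
  stopifnot(inherits(partition, "region_partition"))
  png::writePNG(partition$labels / 4, path)
  invisible(path)
}

#' @rdname write_label_png
#' @param path Path to a label PNG written by [write_label_png()].
#' @export
read_label_png <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  matrix(as.integer(round(g * 4)), nrow = nrow(g))
}
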