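#' @title Vertical cup-to-disc morphometry from segmentation masks
#' @description Binary disc and cup segmentation masks are represented as
#'   integer matrices (`0` background, `1` foreground) with row 1 at the top
#'   of the image; the vertical axis runs along rows, matching upright
#'   fundus photographs. All measurements operate on the largest
#'   4-connected foreground component, which makes them robust to small
#'   spurious islands and interior holes in imperfect segmentations.
#' @name cdr-geometry
NULL

as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- mask
  storage.mode(m) <- "numeric"
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("mask values must be strictly binary (0/1)", call. = FALSE)
  }
  m
}

# largest 4-connected foreground component as a logical matrix;
# NULL for an empty mask
largest_component <- function(mask) {
  m <- as_binary_mask(mask)
  if (!any(m == 1)) return(NULL)
  labels <- EBImage::bwlabel(m)
  sizes <- tabulate(labels[labels > 0])
  labels == which.max(sizes)
}

#' Region of interest around the optic disc
#'
#' Computes the tight bounding box of the largest 4-connected foreground
#' component of a disc mask, expands it by `pad_fraction` of its height and
#' width, and clips it to the raster bounds. Indices are 0-based and
#' half-open: the box covers rows `[top, bottom)` and columns
#' `[left, right)`.
#'
#' @param disc_mask Binary matrix (0/1), row 1 = top of image.
#' @param pad_fraction Non-negative fraction of the box height/width added
#'   on each side before clipping.
#' @return A list of class `roi_box` with integer fields `top`, `bottom`,
#'   `left`, `right`.
#' @export
#' @examples
#' m <- matrix(0L, 10, 10); m[3:6, 4:7] <- 1L
#' extract_roi(m)  # rows [2, 6), cols [3, 7)
extract_roi <- function(disc_mask, pad_fraction = 0) {
  stopifnot(pad_fraction >= 0)
  comp <- largest_component(disc_mask)
  if (is.null(comp)) stop("no disc found: mask has no foreground pixels",
                          call. = FALSE)
  idx <- which(comp, arr.ind = TRUE)
  r0 <- min(idx[, 1]) - 1L  # to 0-based
  r1 <- max(idx[, 1])       # half-open
  c0 <- min(idx[, 2]) - 1L
  c1 <- max(idx[, 2])
  pad_r <- floor(pad_fraction * (r1 - r0))
  pad_c <- floor(pad_fraction * (c1 - c0))
  box <- list(
    top = max(0L, r0 - pad_r),
    bottom = min(nrow(disc_mask), r1 + pad_r),
    left = max(0L, c0 - pad_c),
    right = min(ncol(disc_mask), c1 + pad_c)
  )
  structure(lapply(box, as.integer), class = "roi_box")
}

#' Vertical height of a binary mask
#'
#' Number of rows spanned by the largest 4-connected foreground component
#' (`max_row - min_row + 1`), i.e. the vertical extent, which tolerates
#' interior holes. An empty mask has height 0.
#'
#' @param mask Binary matrix (0/1).
#' @return Integer pixel count.
#' @export
vertical_height <- function(mask) {
  comp <- largest_component(mask)
  if (is.null(comp)) return(0L)
  rows <- which(rowSums(comp) > 0)
  as.integer(max(rows) - min(rows) + 1L)
}

#' Map a pixel measurement back to the original frame
#'
#' A height measured inside a resized ROI is rescaled by the ratio of the
#' original ROI edge to the resized edge and rounded half-up to an integer
#' pixel count.
#'
#' @param measurement_px Measured pixel count in the resized ROI.
#' @param roi An `roi_box` (its vertical extent is the original edge), or a
#'   single number giving the original edge length directly.
#' @param resized_edge Edge length the ROI was resized to (e.g. 256).
#' @return Integer pixel count in original-frame pixels.
#' @export
#' @examples
#' rescale_to_frame(128, 64, 256)  # 32
rescale_to_frame <- function(measurement_px, roi, resized_edge) {
  original_edge <- if (inherits(roi, "roi_box")) roi$bottom - roi$top else roi
  if (measurement_px < 0 || original_edge <= 0 || resized_edge <= 0) {
    stop("pixel counts and edges must be positive", call. = FALSE)
  }
  # round half-up, not banker's rounding
  as.integer(floor(measurement_px * original_edge / resized_edge + 0.5))
}

#' Vertical cup-to-disc ratio from a disc/cup mask pair
#'
#' The cup mask is intersected with the disc mask before measurement
#' (anatomical containment; prevents CDR > 1 from segmentation spill), then
#' CDR = vertical cup height / vertical disc height, heights taken over the
#' largest 4-connected component of each mask.
#'
#' @param disc,cup Binary matrices of identical shape.
#' @return A list of class `cdr_measurement` with `disc_height_px`,
#'   `cup_height_px`, `cdr`, and flags `empty_cup` and `cdr_above_one`
#'   (the latter can only arise if intersection is disabled downstream).
#' @export
#' @examples
#' pair <- synthesize_mask_pair(disc_semi_axes = c(40, 30), cdr_target = 0.6)
#' compute_cdr(pair$disc, pair$cup)
compute_cdr <- function(disc, cup) {
  disc <- as_binary_mask(disc)
  cup <- as_binary_mask(cup)
  if (!all(dim(disc) == dim(cup))) {
    stop("disc and cup masks must share the same shape", call. = FALSE)
  }
  disc_h <- vertical_height(disc)
  if (disc_h == 0L) stop("no disc found: mask has no foreground pixels",
                         call. = FALSE)
  cup_in_disc <- cup * disc
  cup_h <- vertical_height(cup_in_disc)
  cdr <- cup_h / disc_h
  if (cup_h == 0L) {
    warning("empty cup mask: CDR reported as 0", call. = FALSE)
  }
  structure(
    list(disc_height_px = disc_h, cup_height_px = cup_h, cdr = cdr,
         empty_cup = cup_h == 0L, cdr_above_one = cdr > 1),
    class = "cdr_measurement"
  )
}

#' @export
print.cdr_measurement <- function(x, ...) {
  cat(sprintf("<cdr_measurement> disc %d px, cup %d px, CDR %.3f%s\n",
              x$disc_height_px, x$cup_height_px, x$cdr,
              if (x$empty_cup) " (empty cup)" else ""))
  invisible(x)
}

filled_ellipse_mask <- function(shape, center, semi_axes) {
  # semi_axes = c(vertical = b rows, horizontal = a cols); pixel centers at
  # integer coordinates so an axis-aligned ellipse of vertical semi-axis b
  # spans exactly 2b + 1 rows
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- ((rows - center[1]) / semi_axes[1])^2 +
    ((cols - center[2]) / semi_axes[2])^2 <= 1
  mode(inside) <- "integer"
  inside
}

#' Synthesize an axis-aligned elliptical disc/cup mask pair
#'
#' Deterministic fixture generator: the disc is a filled axis-aligned
#' ellipse; the cup is concentric with vertical semi-axis
#' `cdr_target * disc vertical semi-axis` (horizontal semi-axis scaled the
#' same way). A disc of vertical semi-axis `b` rasterized through pixel
#' centers spans exactly `2 b + 1` rows, so [compute_cdr()] round-trips the
#' target within the quantization bound `2 / (2 b + 1)`.
#'
#' @param disc_semi_axes Numeric pair `c(vertical, horizontal)` in pixels.
#' @param cdr_target Target cup-to-disc ratio in \[0, 1\].
#' @param center Pixel pair `c(row, col)`; defaults to the raster center.
#' @param shape Raster dimensions `c(rows, cols)`; defaults to a square
#'   comfortably containing the disc.
#' @return A list with binary matrices `disc` and `cup`.
#' @export
synthesize_mask_pair <- function(disc_semi_axes, cdr_target,
                                 center = NULL, shape = NULL) {
  stopifnot(length(disc_semi_axes) == 2, all(disc_semi_axes > 0),
            cdr_target >= 0, cdr_target <= 1)
  if (is.null(shape)) {
    shape <- rep(2L * ceiling(max(disc_semi_axes)) + 5L, 2)
  }
  if (is.null(center)) center <- (shape + 1) / 2
  if (center[1] - disc_semi_axes[1] < 1 || center[1] + disc_semi_axes[1] > shape[1] ||
      center[2] - disc_semi_axes[2] < 1 || center[2] + disc_semi_axes[2] > shape[2]) {
    stop("disc ellipse does not fit inside the raster", call. = FALSE)
  }
  disc <- filled_ellipse_mask(shape, center, disc_semi_axes)
  cup <- if (cdr_target == 0) {
    matrix(0L, shape[1], shape[2])
  } else {
    filled_ellipse_mask(shape, center, disc_semi_axes * cdr_target)
  }
  list(disc = disc, cup = cup)
}

#' Read or write a binary mask as single-channel PNG
#'
#' Foreground is encoded as 255, background as 0. On read, any grey value
#' of 128 or more counts as foreground.
#'
#' @param path PNG file path.
#' @param mask Binary matrix (0/1).
#' @return `read_mask()` returns a binary integer matrix; `write_mask()`
#'   returns `path` invisibly.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- (img >= 0.5) * 1L
  mode(m) <- "integer"
  m
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_mask(mask)
  png::writePNG(m, path)
  invisible(path)
}
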