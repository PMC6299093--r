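# Fixed-pixel rendering of localization tables, for visualization and QC.
# The colocalization statistic itself works on continuous coordinates; the
# rendered image is never an input to it.

#' Render localizations to a fixed-pixel count image
#'
#' Bins in-ROI localizations into a 2-D histogram whose grid covers the ROI
#' bounding box. Pixels are half-open `[k*p, (k+1)*p)` squares anchored at
#' the bounding-box corner, so the pixel sum always equals the number of
#' in-ROI localizations (conservation).
#'
#' @param locs A `localization_table`.
#' @param roi A `nucleus_roi`; localizations outside it are dropped first
#'   (see [filter_in_roi()]).
#' @param pixel_size Pixel edge in nm (default 20).
#' @return A `rendered_image` with fields `grid` (matrix, rows = y),
#'   `pixel_size`, `origin` (nm of pixel `[1, 1]` corner), `nucleus_id`,
#'   `channel`.
#' @export
render_localizations <- function(locs, roi, pixel_size = 20) {
  stopifnot(pixel_size > 0)
  locs <- filter_in_roi(locs, roi)
  bb <- roi_bbox(roi)
  nx <- max(1L, ceiling((bb[3L] - bb[1L]) / pixel_size))
  ny <- max(1L, ceiling((bb[4L] - bb[2L]) / pixel_size))
  grid <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(locs)) {
    ix <- pmin(floor((locs$x - bb[1L]) / pixel_size) + 1L, nx)
    iy <- pmin(floor((locs$y - bb[2L]) / pixel_size) + 1L, ny)
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    grid <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  structure(
    list(
      nucleus_id = roi$nucleus_id,
      channel = if (nrow(locs)) paste(unique(locs$channel), collapse = "+") else "",
      pixel_size = pixel_size,
      origin = c(bb[1L], bb[2L]),
      grid = grid
    ),
    class = "rendered_image"
  )
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf(
    "<rendered_image '%s' channel=%s> %d x %d px @ %g nm, %d localizations\n",
    x$nucleus_id, x$channel, ncol(x$grid), nrow(x$grid), x$pixel_size,
    sum(x$grid)
  ))
  invisible(x)
}

#' Write a rendered image as 16-bit TIFF
#'
#' Counts are stored directly as 16-bit integers (values above 65535 are
#' clipped with a warning).
#'
#' @param img A `rendered_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rendered_tiff <- function(img, path) {
  stopifnot(inherits(img, "rendered_image"))
  g <- img$grid
  if (any(g > 65535L)) {
    warning("pixel counts above 65535 clipped in 16-bit TIFF", call. = FALSE)
    g <- pmin(g, 65535L)
  }
  tiff::writeTIFF(g / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
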