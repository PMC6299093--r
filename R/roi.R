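# Nucleus regions of interest (ROIs).
#
# An ROI bounds one nucleus in nm coordinates. Four representations are
# supported: axis-aligned rectangle, binary raster mask, closed polygon and
# disc. All downstream geometry (point membership, area, uniform sampling of
# cluster centres under an erosion constraint) dispatches on the type.

#' Rectangular nucleus ROI
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in nm.
#' @param nucleus_id Identifier attached to the ROI.
#' @return A `nucleus_roi` object.
#' @export
roi_rect <- function(xmin, ymin, xmax, ymax, nucleus_id = "roi") {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(
    list(
      type = "rect", nucleus_id = nucleus_id,
      xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax
    ),
    class = "nucleus_roi"
  )
}

#' Raster-mask nucleus ROI
#'
#' The mask is a logical (or 0/1) matrix indexed `[row = y, col = x]`; pixel
#' `[1, 1]` covers the half-open square `[origin, origin + pixel_size)` in
#' each axis. A localization exactly on a pixel edge belongs to the pixel
#' obtained by flooring its coordinate (deterministic boundary rule).
#'
#' @param mask Logical or 0/1 matrix, `TRUE`/1 = inside the nucleus.
#' @param pixel_size Pixel edge length in nm.
#' @param origin Length-2 numeric, nm coordinates of the corner of pixel
#'   `[1, 1]`.
#' @param nucleus_id Identifier.
#' @return A `nucleus_roi` object.
#' @export
roi_mask <- function(mask, pixel_size, origin = c(0, 0), nucleus_id = "roi") {
  stopifnot(is.matrix(mask), pixel_size > 0, length(origin) == 2L)
  mask <- mask != 0
  if (!any(mask)) {
    format_error("empty ROI: mask contains no foreground pixels")
  }
  structure(
    list(
      type = "mask", nucleus_id = nucleus_id,
      mask = mask, pixel_size = pixel_size, origin = as.numeric(origin)
    ),
    class = "nucleus_roi"
  )
}

#' Polygonal nucleus ROI
#'
#' @param vertices Two-column numeric matrix of nm coordinates. The polygon
#'   is closed automatically (a repeated final vertex is dropped) and must
#'   not self-intersect. The boundary counts as inside.
#' @param nucleus_id Identifier.
#' @return A `nucleus_roi` object.
#' @export
roi_polygon <- function(vertices, nucleus_id = "roi") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (all(vertices[1L, ] == vertices[nrow(vertices), ]) && nrow(vertices) > 3L) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  }
  if (polygon_self_intersects(vertices)) {
    format_error("geometry error: polygon is self-intersecting")
  }
  if (abs(shoelace_area(vertices)) <= 0) {
    format_error("empty ROI: polygon has zero area")
  }
  structure(
    list(type = "polygon", nucleus_id = nucleus_id, vertices = vertices),
    class = "nucleus_roi"
  )
}

#' Disc nucleus ROI
#'
#' @param cx,cy Centre in nm.
#' @param radius Radius in nm.
#' @param nucleus_id Identifier.
#' @return A `nucleus_roi` object.
#' @export
roi_disc <- function(cx, cy, radius, nucleus_id = "roi") {
  stopifnot(radius > 0)
  structure(
    list(type = "disc", nucleus_id = nucleus_id, cx = cx, cy = cy, radius = radius),
    class = "nucleus_roi"
  )
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf(
    "<nucleus_roi '%s'> type=%s area=%.4g nm^2\n",
    x$nucleus_id, x$type, roi_area(x)
  ))
  invisible(x)
}

#' ROI area in nm^2
#'
#' Raster masks count foreground pixels times `pixel_size^2`; polygons use
#' the shoelace formula.
#'
#' @param roi A `nucleus_roi`.
#' @return Area in nm^2.
#' @export
roi_area <- function(roi) {
  switch(roi$type,
    rect = (roi$xmax - roi$xmin) * (roi$ymax - roi$ymin),
    mask = sum(roi$mask) * roi$pixel_size^2,
    polygon = abs(shoelace_area(roi$vertices)),
    disc = pi * roi$radius^2,
    stop("unknown ROI type")
  )
}

#' ROI bounding box
#'
#' @param roi A `nucleus_roi`.
#' @return Numeric `c(xmin, ymin, xmax, ymax)` in nm.
#' @export
roi_bbox <- function(roi) {
  switch(roi$type,
    rect = c(roi$xmin, roi$ymin, roi$xmax, roi$ymax),
    mask = c(
      roi$origin[1L], roi$origin[2L],
      roi$origin[1L] + ncol(roi$mask) * roi$pixel_size,
      roi$origin[2L] + nrow(roi$mask) * roi$pixel_size
    ),
    polygon = c(
      min(roi$vertices[, 1L]), min(roi$vertices[, 2L]),
      max(roi$vertices[, 1L]), max(roi$vertices[, 2L])
    ),
    disc = c(
      roi$cx - roi$radius, roi$cy - roi$radius,
      roi$cx + roi$radius, roi$cy + roi$radius
    )
  )
}

#' Point-in-ROI test
#'
#' Vectorized over coordinates. Boundary points count as inside: for masks
#' the floor pixel decides, polygon edges are inclusive.
#'
#' @param roi A `nucleus_roi`.
#' @param x,y Numeric vectors of nm coordinates.
#' @return Logical vector.
#' @export
roi_contains <- function(roi, x, y) {
  switch(roi$type,
    rect = x >= roi$xmin & x <= roi$xmax & y >= roi$ymin & y <= roi$ymax,
    mask = {
      ix <- floor((x - roi$origin[1L]) / roi$pixel_size) + 1
      iy <- floor((y - roi$origin[2L]) / roi$pixel_size) + 1
      ok <- ix >= 1 & ix <= ncol(roi$mask) & iy >= 1 & iy <= nrow(roi$mask)
      inside <- rep(FALSE, length(x))
      if (any(ok)) {
        inside[ok] <- roi$mask[cbind(iy[ok], ix[ok])]
      }
      inside
    },
    polygon = points_in_polygon(roi$vertices, x, y),
    disc = (x - roi$cx)^2 + (y - roi$cy)^2 <= roi$radius^2
  )
}

# Signed shoelace area of a polygon (vertex matrix, not closed).
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

# Even-odd ray casting with inclusive boundary.
points_in_polygon <- function(v, x, y) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  xi <- v[, 1L]; yi <- v[, 2L]
  xj <- v[c(2:n, 1L), 1L]; yj <- v[c(2:n, 1L), 2L]
  tol <- 1e-9
  for (k in seq_len(n)) {
    # boundary check: point within segment bbox and collinear
    dx <- xj[k] - xi[k]; dy <- yj[k] - yi[k]
    cross <- (x - xi[k]) * dy - (y - yi[k]) * dx
    len <- sqrt(dx^2 + dy^2)
    onk <- abs(cross) <= tol * max(len, 1) * len &
      x >= pmin(xi[k], xj[k]) - tol & x <= pmax(xi[k], xj[k]) + tol &
      y >= pmin(yi[k], yj[k]) - tol & y <= pmax(yi[k], yj[k]) + tol
    on_edge <- on_edge | onk
    crosses <- ((yi[k] > y) != (yj[k] > y)) &
      (x < xi[k] + dx * (y - yi[k]) / (yj[k] - yi[k]))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Minimum distance from points to the polygon boundary.
dist_to_polygon_boundary <- function(v, x, y) {
  n <- nrow(v)
  d2 <- rep(Inf, length(x))
  xi <- v[, 1L]; yi <- v[, 2L]
  xj <- v[c(2:n, 1L), 1L]; yj <- v[c(2:n, 1L), 2L]
  for (k in seq_len(n)) {
    dx <- xj[k] - xi[k]; dy <- yj[k] - yi[k]
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - xi[k]) * dx + (y - yi[k]) * dy) / len2)) else 0
    px <- xi[k] + t * dx; py <- yi[k] + t * dy
    d2 <- pmin(d2, (x - px)^2 + (y - py)^2)
  }
  sqrt(d2)
}

# Self-intersection test: any pair of non-adjacent edges crossing.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (b == a + 1L || (a == 1L && b == n)) next
      if (segments_cross(seg[a, 1:2], seg[a, 3:4], seg[b, 1:2], seg[b, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2 && o3 != o4) && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

# TRUE if the whole disc of radius r at (x, y) lies inside the mask ROI:
# every mask pixel intersected by the disc must be foreground.
disc_in_mask <- function(roi, x, y, r) {
  p <- roi$pixel_size
  ix0 <- floor((x - r - roi$origin[1L]) / p) + 1
  ix1 <- floor((x + r - roi$origin[1L]) / p) + 1
  iy0 <- floor((y - r - roi$origin[2L]) / p) + 1
  iy1 <- floor((y + r - roi$origin[2L]) / p) + 1
  if (ix0 < 1 || iy0 < 1 || ix1 > ncol(roi$mask) || iy1 > nrow(roi$mask)) {
    return(FALSE)
  }
  for (iy in iy0:iy1) {
    py0 <- roi$origin[2L] + (iy - 1) * p
    cy <- pmin(pmax(y, py0), py0 + p)
    for (ix in ix0:ix1) {
      px0 <- roi$origin[1L] + (ix - 1) * p
      cx <- pmin(pmax(x, px0), px0 + p)
      if ((cx - x)^2 + (cy - y)^2 < r^2 && !roi$mask[iy, ix]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Uniformly sample n admissible centres for a disc of radius r inside the
# ROI: uniform over the ROI eroded by r. Rectangles and discs are sampled
# analytically; masks and polygons by rejection from the shrunken bbox.
sample_admissible <- function(roi, r, n, max_tries = 100000L, what = "cluster") {
  stopifnot(r >= 0, n >= 0)
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  tol <- 1e-9
  if (roi$type == "rect") {
    lox <- roi$xmin + r; hix <- roi$xmax - r
    loy <- roi$ymin + r; hiy <- roi$ymax - r
    if (lox > hix + tol || loy > hiy + tol) {
      format_error(sprintf(
        "placement error: %s of radius %g nm does not fit inside the ROI", what, r
      ))
    }
    x <- if (hix - lox <= tol) rep((lox + hix) / 2, n) else stats::runif(n, lox, hix)
    y <- if (hiy - loy <= tol) rep((loy + hiy) / 2, n) else stats::runif(n, loy, hiy)
    return(cbind(x, y))
  }
  if (roi$type == "disc") {
    rad <- roi$radius - r
    if (rad < -tol) {
      format_error(sprintf(
        "placement error: %s of radius %g nm does not fit inside the ROI", what, r
      ))
    }
    if (rad <= tol) {
      return(cbind(rep(roi$cx, n), rep(roi$cy, n)))
    }
    rr <- rad * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    return(cbind(roi$cx + rr * cos(th), roi$cy + rr * sin(th)))
  }
  bb <- roi_bbox(roi)
  lox <- bb[1L] + r; hix <- bb[3L] - r
  loy <- bb[2L] + r; hiy <- bb[4L] - r
  if (lox > hix || loy > hiy) {
    format_error(sprintf(
      "placement error: %s of radius %g nm does not fit inside the ROI", what, r
    ))
  }
  out <- matrix(NA_real_, nrow = n, ncol = 2L)
  filled <- 0L
  tries <- 0L
  while (filled < n) {
    m <- max(64L, 2L * (n - filled))
    cx <- stats::runif(m, lox, hix)
    cy <- stats::runif(m, loy, hiy)
    ok <- if (roi$type == "mask") {
      vapply(seq_len(m), function(i) disc_in_mask(roi, cx[i], cy[i], r), logical(1))
    } else {
      points_in_polygon(roi$vertices, cx, cy) &
        dist_to_polygon_boundary(roi$vertices, cx, cy) >= r - tol
    }
    k <- which(ok)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - filled))]
      out[(filled + 1L):(filled + length(take)), ] <- cbind(cx[take], cy[take])
      filled <- filled + length(take)
    }
    tries <- tries + m
    if (tries > max_tries && filled < n) {
      format_error(sprintf(
        "placement error: %s of radius %g nm found no admissible position in the ROI",
        what, r
      ))
    }
  }
  out
}

#' Load a nucleus ROI from a file
#'
#' Raster masks are read from single-page binary TIFF or PNG (any nonzero
#' pixel is foreground; `pixel_size` is required). Polygons are read from a
#' GeoJSON-style JSON file whose `coordinates` field holds the vertex ring
#' in nm.
#'
#' @param path File path (`.tif`/`.tiff`/`.png` raster or `.json`/`.geojson`
#'   polygon).
#' @param pixel_size Pixel edge in nm, required for rasters.
#' @param nucleus_id Identifier; defaults to the file name without extension.
#' @return A `nucleus_roi`.
#' @export
load_roi <- function(path, pixel_size = NULL, nucleus_id = NULL) {
  if (!file.exists(path)) {
    format_error("ROI file not found: ", path)
  }
  nucleus_id <- nucleus_id %||% sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff", "png")) {
    if (is.null(pixel_size)) {
      format_error("pixel_size (nm) is required for raster ROIs")
    }
    img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    roi_mask(img > 0, pixel_size = pixel_size, nucleus_id = nucleus_id)
  } else if (ext %in% c("json", "geojson")) {
    gj <- jsonlite::read_json(path, simplifyVector = TRUE)
    coords <- gj$coordinates %||% gj$geometry$coordinates
    if (is.null(coords)) {
      format_error("polygon JSON has no 'coordinates' field: ", path)
    }
    if (is.list(coords)) coords <- coords[[1L]]
    if (length(dim(coords)) == 3L) coords <- coords[1L, , ]
    roi_polygon(as.matrix(coords), nucleus_id = nucleus_id)
  } else {
    format_error("unsupported ROI file type: .", ext)
  }
}

#' Write a raster-mask ROI to a binary TIFF or PNG
#'
#' @param roi A mask-type `nucleus_roi`.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "nucleus_roi"), roi$type == "mask")
  m <- roi$mask * 1
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a polygon ROI as GeoJSON-style JSON
#'
#' @param roi A polygon-type `nucleus_roi`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_polygon <- function(roi, path) {
  stopifnot(inherits(roi, "nucleus_roi"), roi$type == "polygon")
  jsonlite::write_json(
    list(type = "Polygon", nucleus_id = roi$nucleus_id,
         coordinates = roi$vertices),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
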