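# Localization tables: per-channel, per-nucleus lists of single-molecule
# emission coordinates in nm, the raw input of the colocalization stage.

#' CSV column mapping for localization files
#'
#' Defaults match ThunderSTORM-style headers (`"x [nm]"`, `"y [nm]"`,
#' `"frame"`). Set `unit = "pixel"` together with `pixel_size` to convert
#' camera-pixel coordinates to nm on read.
#'
#' @param x,y Column names holding the coordinates.
#' @param frame Column name of the acquisition frame index, or `NULL`.
#' @param channel Column name of the channel label, or `NULL` (constant
#'   label supplied at read time).
#' @param nucleus Column name of the nucleus id, or `NULL`.
#' @param unit `"nm"` (default) or `"pixel"`.
#' @param pixel_size Camera pixel size in nm, required when
#'   `unit = "pixel"`.
#' @return A `loc_dialect` list.
#' @export
loc_dialect <- function(x = "x [nm]", y = "y [nm]", frame = "frame",
                        channel = NULL, nucleus = NULL,
                        unit = c("nm", "pixel"), pixel_size = NULL) {
  unit <- match.arg(unit)
  if (unit == "pixel" && is.null(pixel_size)) {
    format_error("dialect with unit='pixel' requires pixel_size (nm)")
  }
  structure(
    list(x = x, y = y, frame = frame, channel = channel, nucleus = nucleus,
         unit = unit, pixel_size = pixel_size),
    class = "loc_dialect"
  )
}

#' Construct a localization table
#'
#' @param nucleus_id Nucleus identifier (recycled).
#' @param channel Channel label (recycled), e.g. `"gH2AX"`, `"S9.6"`.
#' @param x,y Coordinates in nm; must be finite.
#' @param frame Optional integer acquisition frame.
#' @return A data frame of class `localization_table` with columns
#'   `nucleus_id`, `channel`, `x`, `y`, `frame`.
#' @export
localization_table <- function(nucleus_id, channel, x, y, frame = NA_integer_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    format_error("x and y must have equal length")
  }
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y)))) {
    format_error("localization coordinates must be finite")
  }
  df <- data.frame(
    nucleus_id = rep_len(as.character(nucleus_id), length(x)),
    channel = rep_len(as.character(channel), length(x)),
    x = x, y = y,
    frame = rep_len(as.integer(frame), length(x)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Read a localization table from CSV
#'
#' Applies the column mapping in `dialect`, converts pixel coordinates to nm
#' when the dialect says so, and drops rows with non-finite coordinates
#' (the dropped count is reported and attached as attribute `n_dropped`).
#'
#' @param path CSV file path.
#' @param dialect A [loc_dialect()] column mapping.
#' @param channel Constant channel label used when the dialect maps no
#'   channel column.
#' @param nucleus_id Constant nucleus id used when the dialect maps no
#'   nucleus column.
#' @return A `localization_table`.
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               channel = "ch1", nucleus_id = "n1") {
  if (!file.exists(path)) {
    format_error("localization file not found: ", path)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty localization file: ", path, call. = FALSE)
    return(localization_table(character(0), character(0), numeric(0), numeric(0)))
  }
  for (col in c("x", "y")) {
    if (!(dialect[[col]] %in% names(raw))) {
      format_error(sprintf(
        "format error: mapped column '%s' (for %s) missing in %s",
        dialect[[col]], col, path
      ))
    }
  }
  x <- suppressWarnings(as.numeric(raw[[dialect$x]]))
  y <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_localizations: dropped %d non-finite row(s)", n_dropped))
  }
  if (dialect$unit == "pixel") {
    x <- x * dialect$pixel_size
    y <- y * dialect$pixel_size
  }
  fr <- if (!is.null(dialect$frame) && dialect$frame %in% names(raw)) {
    suppressWarnings(as.integer(raw[[dialect$frame]]))
  } else {
    NA_integer_
  }
  ch <- if (!is.null(dialect$channel) && dialect$channel %in% names(raw)) {
    as.character(raw[[dialect$channel]])
  } else {
    channel
  }
  nid <- if (!is.null(dialect$nucleus) && dialect$nucleus %in% names(raw)) {
    as.character(raw[[dialect$nucleus]])
  } else {
    nucleus_id
  }
  ch <- rep_len(ch, nrow(raw)); nid <- rep_len(nid, nrow(raw))
  fr <- rep_len(fr, nrow(raw))
  out <- localization_table(nid[keep], ch[keep], x[keep], y[keep], fr[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a localization table to CSV
#'
#' Writes nm coordinates under the dialect's column names, so that
#' [read_localizations()] with the same dialect round-trips the table.
#'
#' @param locs A `localization_table`.
#' @param path Output CSV path.
#' @param dialect Column mapping; pixel-unit dialects are refused (writing
#'   is always in nm).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, dialect = loc_dialect()) {
  stopifnot(inherits(locs, "localization_table"))
  if (dialect$unit != "nm") {
    format_error("write_localizations writes nm coordinates only")
  }
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = locs$x, b = locs$y, frame = locs$frame,
    channel = locs$channel, nucleus_id = locs$nucleus_id
  )
  names(out)[1:2] <- c(dialect$x, dialect$y)
  if (!is.null(dialect$frame)) names(out)[3] <- dialect$frame
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only localizations inside an ROI
#'
#' Records outside the ROI are dropped; their count is reported via
#' `message()` and attached as attribute `n_dropped`. The boundary rule is
#' inclusive (see [roi_contains()]), so the dropped set is deterministic.
#'
#' @param locs A `localization_table`.
#' @param roi A `nucleus_roi`.
#' @return Filtered `localization_table`.
#' @export
filter_in_roi <- function(locs, roi) {
  stopifnot(inherits(locs, "localization_table"), inherits(roi, "nucleus_roi"))
  if (nrow(locs) == 0L) {
    attr(locs, "n_dropped") <- 0L
    return(locs)
  }
  keep <- roi_contains(roi, locs$x, locs$y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf(
      "filter_in_roi: dropped %d localization(s) outside ROI '%s'",
      n_dropped, roi$nucleus_id
    ))
  }
  out <- locs[keep, , drop = FALSE]
  class(out) <- c("localization_table", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Convex-hull fallback ROI from the localizations themselves
#'
#' For data sets shipped without a nucleus mask. This is a non-canonical
#' stand-in: the hull underestimates the nucleus wherever localizations are
#' sparse near the membrane, which inflates the randomization density
#' slightly. A warning marks every use.
#'
#' @param locs A `localization_table` (all channels pooled is recommended).
#' @param nucleus_id Identifier for the resulting ROI.
#' @return A polygon `nucleus_roi`.
#' @export
convex_hull_roi <- function(locs, nucleus_id = "hull") {
  stopifnot(inherits(locs, "localization_table"))
  if (nrow(locs) < 3L) {
    format_error("need at least 3 localizations for a convex-hull ROI")
  }
  warning("convex-hull ROI is a non-canonical fallback for a measured nucleus mask",
          call. = FALSE)
  h <- grDevices::chull(locs$x, locs$y)
  roi_polygon(cbind(locs$x[h], locs$y[h]), nucleus_id = nucleus_id)
}
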