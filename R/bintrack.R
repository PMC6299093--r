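# Fixed-width genomic bin tracks (bedGraph convention: 0-based half-open
# coordinates) and cut-site tables (BED; score = cleavage rank, name tag =
# genic/nongenic).

#' Construct a bin track
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open bin coordinates in bp.
#' @param value Numeric value per bin (counts or log2 ratios).
#' @param bin_width Nominal bin width in bp; inferred as the modal width
#'   when `NULL`. All bins except possibly the last of each chromosome must
#'   have this width.
#' @return A data frame of class `bin_track`, sorted by (chrom, start),
#'   with attribute `bin_width`.
#' @export
bin_track <- function(chrom, start, end, value, bin_width = NULL) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) {
    format_error("bin track has bins with end <= start")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    if (any(df$start[sel][-1L] < df$end[sel][-sum(sel)])) {
      format_error("bin track has overlapping bins on ", ch)
    }
  }
  w <- df$end - df$start
  if (is.null(bin_width)) {
    bin_width <- as.numeric(names(sort(table(w), decreasing = TRUE))[1L])
  }
  attr(df, "bin_width") <- bin_width
  class(df) <- c("bin_track", "data.frame")
  df
}

#' Nominal bin width of a track
#' @param track A `bin_track`.
#' @return Width in bp.
#' @export
bin_width <- function(track) {
  attr(track, "bin_width")
}

#' Read a bedGraph file into a bin track
#'
#' @param path bedGraph path (4 columns; track/header lines are handled by
#'   the reader).
#' @param bin_width Nominal bin width; inferred when `NULL`.
#' @return A `bin_track`.
#' @export
read_bedgraph <- function(path, bin_width = NULL) {
  if (!file.exists(path)) {
    format_error("bedGraph file not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  bin_track(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$score,
    bin_width = bin_width
  )
}

#' Write a bin track as bedGraph
#'
#' @param track A `bin_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "bin_track"))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Construct a cut-site table
#'
#' @param chrom Chromosome per site.
#' @param position 0-based bp coordinate of the cut.
#' @param cleavage_score Real-valued cleavage rank score (higher = more
#'   efficiently cut).
#' @param genic Logical: does the site fall in a gene body?
#' @param site_id Unique identifiers; autogenerated when `NULL`.
#' @return A data frame of class `cut_site_table`.
#' @export
cut_site_table <- function(chrom, position, cleavage_score, genic,
                           site_id = NULL) {
  n <- length(position)
  site_id <- site_id %||% sprintf("site_%03d", seq_len(n))
  if (anyDuplicated(site_id)) {
    format_error("site_ids must be unique")
  }
  df <- data.frame(
    site_id = as.character(site_id),
    chrom = as.character(chrom),
    position = as.numeric(position),
    cleavage_score = as.numeric(cleavage_score),
    genic = as.logical(genic),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cut_site_table", "data.frame")
  df
}

#' Read cut sites from BED
#'
#' Expects BED6-style records of width 1 at the cut coordinate, with the
#' score column holding the cleavage rank and the name column carrying a
#' `genic` / `nongenic` tag (optionally prefixed with a site id, e.g.
#' `site_007|genic`).
#'
#' @param path BED path.
#' @return A `cut_site_table`.
#' @export
read_cut_sites <- function(path) {
  if (!file.exists(path)) {
    format_error("cut-site BED not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) {
    format_error("cut-site BED needs a name column with a genic/nongenic tag")
  }
  genic <- !grepl("nongenic", nm) & grepl("genic", nm)
  ids <- sub("\\|?(non)?genic$", "", nm)
  if (any(ids == "") || anyDuplicated(ids)) {
    ids <- sprintf("site_%03d", seq_along(nm))
  }
  cut_site_table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    cleavage_score = as.numeric(S4Vectors::mcols(gr)$score),
    genic = genic,
    site_id = ids
  )
}

#' Write cut sites as BED
#'
#' @param sites A `cut_site_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cut_sites <- function(sites, path) {
  stopifnot(inherits(sites, "cut_site_table"))
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = 1L),
    name = paste0(sites$site_id, "|", ifelse(sites$genic, "genic", "nongenic")),
    score = sites$cleavage_score
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
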