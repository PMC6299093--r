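# DSB-proximal enrichment profile: RPKM normalization, log2 cut/uncut
# tracks, assignment of bins to distance windows around top-ranked cut
# sites under a minimum-overlap rule, per-site window means, and
# genic/nongenic stratification with signed-rank testing.

#' RPKM-normalize a count track
#'
#' `value' = count / ((width/1000) * (total_reads/1e6))`, the
#' reads-per-kilobase-per-million convention applied per bin (the actual
#' width of each bin is used, so a short terminal bin is scaled correctly).
#'
#' @param track A `bin_track` of raw counts.
#' @param total_reads Library size; must be positive. Defaults to the sum
#'   of the track's counts.
#' @return A `bin_track` of RPKM values.
#' @export
normalize_track <- function(track, total_reads = sum(track$value)) {
  stopifnot(inherits(track, "bin_track"))
  if (!is.finite(total_reads) || total_reads <= 0) {
    format_error("parameter error: total_reads must be > 0")
  }
  w <- track$end - track$start
  bin_track(track$chrom, track$start, track$end,
            track$value / ((w / 1000) * (total_reads / 1e6)),
            bin_width = bin_width(track))
}

#' log2 cut/uncut ratio track
#'
#' `value = log2((cut + pseudocount) / (uncut + pseudocount))` per bin. The
#' two tracks must share an identical bin grid.
#'
#' @param cut,uncut `bin_track`s on the same grid.
#' @param pseudocount Positive pseudocount added to both conditions
#'   (default 1, on the normalized scale).
#' @return A `bin_track` of log2 ratios.
#' @export
log2_ratio_track <- function(cut, uncut, pseudocount = 1) {
  stopifnot(inherits(cut, "bin_track"), inherits(uncut, "bin_track"))
  if (pseudocount <= 0) {
    format_error("parameter error: pseudocount must be > 0")
  }
  if (nrow(cut) != nrow(uncut) ||
      !all(cut$chrom == uncut$chrom) ||
      !all(cut$start == uncut$start) ||
      !all(cut$end == uncut$end)) {
    i <- if (nrow(cut) != nrow(uncut)) {
      NA_integer_
    } else {
      which(cut$chrom != uncut$chrom | cut$start != uncut$start |
              cut$end != uncut$end)[1L]
    }
    format_error(
      "alignment error: cut and uncut tracks have different bin grids",
      if (!is.na(i)) sprintf(" (first mismatch at row %d: %s:%g-%g vs %s:%g-%g)",
                             i, cut$chrom[i], cut$start[i], cut$end[i],
                             uncut$chrom[i], uncut$start[i], uncut$end[i])
      else sprintf(" (%d vs %d bins)", nrow(cut), nrow(uncut))
    )
  }
  # difference of logs rather than log of the quotient: mathematically the
  # same, but bitwise antisymmetric under swapping the two conditions
  bin_track(cut$chrom, cut$start, cut$end,
            log2(cut$value + pseudocount) - log2(uncut$value + pseudocount),
            bin_width = bin_width(cut))
}

#' Select the top-k cut sites by cleavage score
#'
#' Ties at the boundary are broken by (chrom, position) lexicographic
#' order, deterministically.
#'
#' @param sites A `cut_site_table`.
#' @param k Number of sites to keep (default 50).
#' @return A `cut_site_table` of `min(k, nrow(sites))` sites; a warning is
#'   issued when `k` exceeds the table size.
#' @export
select_top_sites <- function(sites, k = 50) {
  stopifnot(inherits(sites, "cut_site_table"), k >= 1)
  if (k > nrow(sites)) {
    warning(sprintf("k = %d exceeds the %d available sites; keeping all",
                    k, nrow(sites)), call. = FALSE)
    k <- nrow(sites)
  }
  ord <- order(-sites$cleavage_score, sites$chrom, sites$position)
  out <- sites[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cut_site_table", "data.frame")
  out
}

#' Canonical distance windows around a cut site
#'
#' Five half-open windows on absolute distance from the cut, tiling
#' 0-2500 bp: 0-0.5, 0.5-1, 1-1.5, 1.5-2 and 2-2.5 kb.
#'
#' @param breaks Window boundaries in bp (default `seq(0, 2500, 500)`).
#' @return Data frame with columns `interval` (label), `lower`, `upper`
#'   (bp, half-open `[lower, upper)`).
#' @export
distance_intervals <- function(breaks = seq(0, 2500, by = 500)) {
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1L]
  kb <- function(x) sub("\\.?0+$", "", sprintf("%.1f", x / 1000))
  data.frame(
    interval = paste0(kb(lower), "-", kb(upper)),
    lower = lower, upper = upper,
    stringsAsFactors = FALSE
  )
}

#' Assign track bins to per-site distance windows
#'
#' For each site and window `[lower, upper)` the genomic footprint is the
#' two-sided union `[pos - upper, pos - lower) U [pos + lower, pos + upper)`
#' on the site's chromosome. A bin is assigned to that (site, window) pair
#' iff its total overlap with the footprint is at least
#' `min_overlap_frac * bin_width(track)` bp (`>=` comparison, so a 45-bp
#' overlap of a 50-bp bin passes at the default 0.9). Sites are treated
#' independently: one bin may serve several sites, but it can satisfy the
#' rule for at most one window of a given site because the windows are
#' disjoint and `min_overlap_frac > 0.5`.
#'
#' @param track A `bin_track` (typically the log2 ratio track).
#' @param sites A `cut_site_table`.
#' @param intervals Distance windows from [distance_intervals()].
#' @param min_overlap_frac Minimum overlap as a fraction of the nominal bin
#'   width, in `(0, 1]` (default 0.9).
#' @return Data frame of assignments: `site_id`, `interval`, `chrom`,
#'   `start`, `end`, `value`.
#' @export
assign_bins <- function(track, sites, intervals = distance_intervals(),
                        min_overlap_frac = 0.9) {
  stopifnot(inherits(track, "bin_track"), inherits(sites, "cut_site_table"))
  if (min_overlap_frac <= 0 || min_overlap_frac > 1) {
    format_error("parameter error: min_overlap_frac must be in (0, 1]")
  }
  bw <- bin_width(track)
  min_bp <- min_overlap_frac * bw

  # footprints: 2 ranges per (site, window), clipped at position 0
  n_s <- nrow(sites)
  n_i <- nrow(intervals)
  site_idx <- rep(seq_len(n_s), each = 2L * n_i)
  int_idx <- rep(rep(seq_len(n_i), each = 2L), times = n_s)
  side <- rep(c(-1, 1), times = n_s * n_i)
  pos <- sites$position[site_idx]
  lo <- intervals$lower[int_idx]
  up <- intervals$upper[int_idx]
  fp_start <- ifelse(side < 0, pos - up, pos + lo)
  fp_end <- ifelse(side < 0, pos - lo, pos + up)
  fp_start <- pmax(fp_start, 0)
  keep <- fp_end > fp_start
  fp <- GenomicRanges::GRanges(
    seqnames = sites$chrom[site_idx][keep],
    ranges = IRanges::IRanges(start = fp_start[keep] + 1L, end = fp_end[keep])
  )
  fp_site <- site_idx[keep]
  fp_int <- int_idx[keep]

  bins <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  hits <- GenomicRanges::findOverlaps(bins, fp, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(site_id = character(0), interval = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(bins)[q], GenomicRanges::ranges(fp)[s]
  ))
  # a footprint is a union of two ranges: pool overlap per (bin, site, window)
  key <- paste(q, fp_site[s], fp_int[s], sep = "\r")
  tot <- rowsum(ov, key)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  qb <- as.integer(vapply(parts, `[[`, "", 1L))
  qs <- as.integer(vapply(parts, `[[`, "", 2L))
  qi <- as.integer(vapply(parts, `[[`, "", 3L))
  pass <- tot[, 1L] >= min_bp
  out <- data.frame(
    site_id = sites$site_id[qs[pass]],
    interval = intervals$interval[qi[pass]],
    chrom = track$chrom[qb[pass]],
    start = track$start[qb[pass]],
    end = track$end[qb[pass]],
    value = track$value[qb[pass]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$site_id, match(out$interval, intervals$interval), out$start), ]
  rownames(out) <- NULL
  out
}

#' Per-site, per-window mean values
#'
#' Arithmetic mean of the assigned bin values for every (site, window)
#' pair; pairs with no assigned bins are omitted (their count is attached
#' as attribute `n_omitted` when `sites` is supplied).
#'
#' @param assignments Output of [assign_bins()].
#' @param sites Optional `cut_site_table` used to count omitted pairs.
#' @param intervals Optional window table used to count omitted pairs.
#' @return Data frame: `site_id`, `interval`, `mean_log2`, `n_bins`.
#' @export
site_interval_means <- function(assignments, sites = NULL, intervals = NULL) {
  if (nrow(assignments) == 0L) {
    out <- data.frame(site_id = character(0), interval = character(0),
                      mean_log2 = numeric(0), n_bins = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- interaction(assignments$site_id, assignments$interval, drop = TRUE)
    m <- tapply(assignments$value, key, mean)
    n <- tapply(assignments$value, key, length)
    first <- !duplicated(key)
    out <- data.frame(
      site_id = assignments$site_id[first],
      interval = assignments$interval[first],
      mean_log2 = as.numeric(m[as.character(key[first])]),
      n_bins = as.integer(n[as.character(key[first])]),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$site_id, out$interval), ]
    rownames(out) <- NULL
  }
  if (!is.null(sites) && !is.null(intervals)) {
    attr(out, "n_omitted") <- nrow(sites) * nrow(intervals) - nrow(out)
  }
  out
}

#' Stratified window summaries with signed-rank tests
#'
#' For each distance window, overall and split by genic context, reports
#' the median, quartiles and n of the per-site mean log2 ratios, plus a
#' two-sided one-sample Wilcoxon signed-rank test against 0 (see
#' [signed_rank_test()]). Windows with fewer than `min_sites` contributing
#' sites, or with no nonzero values, keep their summary but the test is
#' withheld (`p = NA`) with a warning.
#'
#' @param enrichments Output of [site_interval_means()].
#' @param sites `cut_site_table` providing the genic flags.
#' @param strata Which strata to report; any of `"all"`, `"genic"`,
#'   `"nongenic"`.
#' @param min_sites Minimum sites per window for a test (default 5).
#' @param bonferroni Multiply p-values by the number of windows (capped at
#'   1)? Off by default.
#' @param mu Null value tested against (default 0).
#' @return Data frame: `stratum`, `interval`, `n`, `median`, `q25`, `q75`,
#'   `p`.
#' @export
stratify_and_test <- function(enrichments, sites,
                              strata = c("all", "genic", "nongenic"),
                              min_sites = 5, bonferroni = FALSE, mu = 0) {
  stopifnot(inherits(sites, "cut_site_table"))
  strata <- match.arg(strata, several.ok = TRUE)
  genic_of <- stats::setNames(sites$genic, sites$site_id)
  enrichments$genic <- genic_of[enrichments$site_id]
  ivals <- unique(enrichments$interval)
  rows <- list()
  for (st in strata) {
    sel <- switch(st,
      all = rep(TRUE, nrow(enrichments)),
      genic = enrichments$genic,
      nongenic = !enrichments$genic
    )
    for (iv in ivals) {
      x <- enrichments$mean_log2[sel & enrichments$interval == iv]
      n <- length(x)
      qs <- if (n) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3L)
      p <- NA_real_
      if (n >= min_sites) {
        sr <- signed_rank_test(x, mu = mu)
        if (is.na(sr$p.value)) {
          warning(sprintf(
            "signed-rank test withheld for window %s (%s): no nonzero differences",
            iv, st), call. = FALSE)
        }
        p <- sr$p.value
      } else {
        warning(sprintf(
          "signed-rank test withheld for window %s (%s): %d site(s) < %d",
          iv, st, n, min_sites), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, interval = iv, n = n,
        median = qs[2L], q25 = qs[1L], q75 = qs[3L], p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) {
    k <- length(ivals)
    out$p <- pmin(out$p * k, 1)
  }
  out
}

#' Full enrichment profile from count tracks to tested windows
#'
#' The canonical pipeline: RPKM-normalize both conditions, form the log2
#' cut/uncut track, keep the top-`top_k` cut sites, assign bins to distance
#' windows under the minimum-overlap rule, average per site and window,
#' and test each window (overall + genic/nongenic) against 0.
#'
#' @param cut,uncut `bin_track`s of counts (or precomputed values, see
#'   `tracks_are_log2`).
#' @param sites A `cut_site_table`.
#' @param top_k Number of top-ranked sites analyzed (default 50).
#' @param intervals Distance windows (default [distance_intervals()]).
#' @param min_overlap_frac Minimum bin-overlap fraction (default 0.9).
#' @param pseudocount Pseudocount for the log2 ratio (default 1).
#' @param total_reads_cut,total_reads_uncut Library sizes; default to each
#'   track's total.
#' @param tracks_are_log2 When `TRUE`, `cut` already holds a log2 ratio
#'   track and `uncut` is ignored.
#' @param bonferroni Passed to [stratify_and_test()].
#' @return List: `track` (log2 `bin_track`), `sites` (top-k table),
#'   `per_site` (site x window means), `summary` (stratified tests).
#' @export
drip_profile <- function(cut, uncut = NULL, sites, top_k = 50,
                         intervals = distance_intervals(),
                         min_overlap_frac = 0.9, pseudocount = 1,
                         total_reads_cut = NULL, total_reads_uncut = NULL,
                         tracks_are_log2 = FALSE, bonferroni = FALSE) {
  if (tracks_are_log2) {
    lr <- cut
  } else {
    stopifnot(inherits(uncut, "bin_track"))
    cut_n <- normalize_track(cut, total_reads_cut %||% sum(cut$value))
    uncut_n <- normalize_track(uncut, total_reads_uncut %||% sum(uncut$value))
    lr <- log2_ratio_track(cut_n, uncut_n, pseudocount = pseudocount)
  }
  top <- select_top_sites(sites, k = top_k)
  asg <- assign_bins(lr, top, intervals = intervals,
                     min_overlap_frac = min_overlap_frac)
  per_site <- site_interval_means(asg, sites = top, intervals = intervals)
  summary <- suppressWarnings(
    stratify_and_test(per_site, top, bonferroni = bonferroni)
  )
  list(track = lr, sites = top, per_site = per_site, summary = summary)
}
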