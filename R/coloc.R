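# The two-channel colocalization statistic: real cluster overlaps divided by
# the mean overlap count across Monte-Carlo randomizations of the clusters
# within the same nucleus ROI. One ratio per nucleus; cohorts of nuclei are
# summarized as mean +/- s.e.m. with a Welch t-test between groups.

#' Count two-channel cluster overlaps
#'
#' Two clusters overlap when their centroid distance does not exceed the sum
#' of their effective radii (disc intersection). The default counting unit
#' is unordered intersecting pairs; `unit = "matched"` instead counts
#' clusters of `a` having at least one partner in `b` (a QC alternative,
#' not symmetric).
#'
#' @param a,b `cluster_set`s from the same nucleus, different channels.
#' @param unit `"pairs"` (default) or `"matched"`.
#' @return Integer overlap count; 0 when either set is empty.
#' @export
count_overlaps <- function(a, b, unit = c("pairs", "matched")) {
  stopifnot(inherits(a, "cluster_set"), inherits(b, "cluster_set"))
  unit <- match.arg(unit)
  na <- nrow(a$clusters)
  nb <- nrow(b$clusters)
  if (na == 0L || nb == 0L) {
    return(0L)
  }
  dx <- outer(a$clusters$x, b$clusters$x, "-")
  dy <- outer(a$clusters$y, b$clusters$y, "-")
  thr <- outer(a$clusters$radius, b$clusters$radius, "+")
  hit <- (dx * dx + dy * dy) <= thr * thr
  if (unit == "pairs") {
    sum(hit)
  } else {
    sum(rowSums(hit) > 0L)
  }
}

#' Randomly rearrange clusters within the nucleus ROI
#'
#' Each cluster is independently translated (no rotation or reshaping) to a
#' uniformly random admissible position: its centroid is drawn uniformly
#' from the ROI eroded by the cluster's radius, so the whole disc stays
#' inside the nucleus. Counts, radii, member offsets and localization
#' numbers are preserved. Consumes the current RNG stream; seed outside or
#' via [normalized_overlap_ratio()].
#'
#' @param s A `cluster_set`.
#' @param roi The `nucleus_roi` to rearrange within.
#' @return A `cluster_set` with new centroids.
#' @export
randomize_clusters <- function(s, roi) {
  stopifnot(inherits(s, "cluster_set"), inherits(roi, "nucleus_roi"))
  cl <- s$clusters
  n <- nrow(cl)
  if (n == 0L) {
    return(s)
  }
  if (roi$type == "rect") {
    # all clusters share the analytic eroded-rectangle form; vectorize by radius
    lox <- roi$xmin + cl$radius; hix <- roi$xmax - cl$radius
    loy <- roi$ymin + cl$radius; hiy <- roi$ymax - cl$radius
    bad <- lox > hix + 1e-9 | loy > hiy + 1e-9
    if (any(bad)) {
      format_error(sprintf(
        "placement error: cluster '%s' (radius %g nm) does not fit inside the ROI",
        cl$cluster_id[which(bad)[1L]], cl$radius[which(bad)[1L]]
      ))
    }
    u <- stats::runif(n); v <- stats::runif(n)
    cl$x <- ifelse(hix - lox <= 1e-9, (lox + hix) / 2, lox + u * (hix - lox))
    cl$y <- ifelse(hiy - loy <= 1e-9, (loy + hiy) / 2, loy + v * (hiy - loy))
  } else {
    for (i in seq_len(n)) {
      p <- tryCatch(
        sample_admissible(roi, cl$radius[i], 1L,
                          what = sprintf("cluster '%s'", cl$cluster_id[i])),
        error = function(e) stop(e)
      )
      cl$x[i] <- p[1L, 1L]
      cl$y[i] <- p[1L, 2L]
    }
  }
  cluster_set(s$nucleus_id, s$channel, cl, members = s$members, params = s$params)
}

#' Normalized overlap ratio for one nucleus
#'
#' Computes the real overlap count between channels, then builds the
#' Monte-Carlo null: in each of `n_sim` simulations the clusters are
#' randomly rearranged within the ROI and overlaps are re-counted. The
#' normalized ratio is `n_real / mean(random counts)`. By default both
#' channels are rearranged in every simulation, so the null carries both
#' channels' cluster sizes and numbers (this is how the broader spatial
#' spread of one marker relative to the other is absorbed into the
#' baseline); `randomize` can restrict rearrangement to one channel.
#'
#' Degenerate nuclei (`mean_random == 0` with real overlaps present) are
#' flagged `"null-degenerate"` and carry an `NA` ratio; when both real and
#' random counts are zero the ratio is defined as 0 with flag
#' `"both-zero"`. Both flags exclude the nucleus from cohort summaries.
#'
#' @param a,b `cluster_set`s of the two channels, same nucleus.
#' @param roi The `nucleus_roi`.
#' @param n_sim Number of random simulations (default 20).
#' @param seed Integer seed making the result fully reproducible, or `NULL`
#'   to consume the current RNG stream.
#' @param randomize Which channels to rearrange per simulation: `"both"`
#'   (default), `"a"` or `"b"`.
#' @param unit Overlap counting unit, see [count_overlaps()].
#' @return A `coloc_result` list: `nucleus_id`, `channel_pair`, `n_real`,
#'   `random_counts` (length `n_sim`), `mean_random`, `ratio`, `flag`,
#'   `n_clusters_a`, `n_clusters_b`, `n_sim`, `seed`.
#' @export
normalized_overlap_ratio <- function(a, b, roi, n_sim = 20, seed = NULL,
                                     randomize = c("both", "a", "b"),
                                     unit = c("pairs", "matched")) {
  stopifnot(n_sim >= 1)
  randomize <- match.arg(randomize)
  unit <- match.arg(unit)
  if (!identical(a$nucleus_id, b$nucleus_id)) {
    format_error("cluster sets come from different nuclei: ",
                 a$nucleus_id, " vs ", b$nucleus_id)
  }
  n_real <- count_overlaps(a, b, unit = unit)
  random_counts <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      ra <- if (randomize %in% c("both", "a")) randomize_clusters(a, roi) else a
      rb <- if (randomize %in% c("both", "b")) randomize_clusters(b, roi) else b
      as.integer(count_overlaps(ra, rb, unit = unit))
    }, integer(1))
  })
  mean_random <- mean(random_counts)
  if (mean_random > 0) {
    ratio <- n_real / mean_random
    flag <- "ok"
  } else if (n_real > 0) {
    ratio <- NA_real_
    flag <- "null-degenerate"
  } else {
    ratio <- 0
    flag <- "both-zero"
  }
  structure(
    list(
      nucleus_id = a$nucleus_id,
      channel_pair = c(a$channel, b$channel),
      n_real = as.integer(n_real),
      random_counts = random_counts,
      mean_random = mean_random,
      ratio = ratio,
      flag = flag,
      n_clusters_a = nrow(a$clusters),
      n_clusters_b = nrow(b$clusters),
      n_sim = as.integer(n_sim),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result '%s' %s~%s> real=%d mean_random=%.3f ratio=%s [%s]\n",
    x$nucleus_id, x$channel_pair[1L], x$channel_pair[2L], x$n_real,
    x$mean_random, format(round(x$ratio, 4)), x$flag
  ))
  invisible(x)
}

#' Tabulate a list of coloc results
#'
#' @param results List of `coloc_result`s.
#' @return Data frame with one row per nucleus: `nucleus_id`, `pair`,
#'   `n_clusters_a`, `n_clusters_b`, `n_real`, `mean_random`, `ratio`,
#'   `flag`, `n_sim`, `seed`.
#' @export
coloc_results_table <- function(results) {
  stopifnot(length(results) > 0L)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      nucleus_id = r$nucleus_id,
      pair = paste(r$channel_pair, collapse = "~"),
      n_clusters_a = r$n_clusters_a,
      n_clusters_b = r$n_clusters_b,
      n_real = r$n_real,
      mean_random = r$mean_random,
      ratio = r$ratio,
      flag = r$flag,
      n_sim = r$n_sim,
      seed = r$seed,
      stringsAsFactors = FALSE
    )
  }))
}

#' Cohort summary and two-group Welch test of normalized ratios
#'
#' Summarizes valid (flag `"ok"`) normalized ratios per group as mean,
#' s.e.m. and n. With exactly two groups that both have at least two valid
#' nuclei, a Welch two-sample two-tailed t-test compares them; otherwise
#' the test is withheld with a warning.
#'
#' @param values Numeric vector of normalized ratios (or a data frame from
#'   [coloc_results_table()], in which case `ratio` and `flag` columns are
#'   used).
#' @param groups Group label per value.
#' @param flags Optional flag per value; non-`"ok"` entries are excluded
#'   and counted.
#' @return A list with `groups` (data frame: group, n, mean, sem),
#'   `n_excluded`, and `test` (list with `t`, `df`, `p`) or `NULL`.
#' @export
cohort_summary <- function(values, groups, flags = NULL) {
  if (is.data.frame(values)) {
    flags <- flags %||% values$flag
    values <- values$ratio
  }
  stopifnot(length(values) == length(groups))
  flags <- flags %||% rep("ok", length(values))
  valid <- flags == "ok" & !is.na(values)
  n_excluded <- sum(!valid)
  v <- values[valid]
  g <- as.character(groups)[valid]
  tab <- do.call(rbind, lapply(split(v, g), function(x) {
    data.frame(
      n = length(x),
      mean = mean(x),
      sem = if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
    )
  }))
  tab <- data.frame(group = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  test <- NULL
  if (nrow(tab) == 2L && all(tab$n >= 2L)) {
    ht <- stats::t.test(v[g == tab$group[1L]], v[g == tab$group[2L]],
                        var.equal = FALSE, alternative = "two.sided")
    test <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
  } else {
    warning("Welch test withheld: need exactly 2 groups with >= 2 valid nuclei each",
            call. = FALSE)
  }
  list(groups = tab, n_excluded = n_excluded, test = test)
}

#' Run the colocalization statistic over a simulated cohort
#'
#' Convenience wrapper: for each nucleus from [simulate_smlm_cohort()]
#' (or a compatible list), builds the two channels' cluster sets either
#' from the simulation ground truth or by density-based detection on the
#' localizations, and computes the normalized overlap ratio with a
#' per-nucleus child seed derived from `seed` (see [nucleus_seed()]).
#'
#' @param nuclei List of nuclei as returned by [simulate_smlm_cohort()].
#' @param n_sim Randomizations per nucleus (default 20).
#' @param seed Root seed for the run.
#' @param clusters `"truth"` (default; use the simulator's ground-truth
#'   clusters) or `"detect"` (run [detect_clusters()] on the
#'   localizations).
#' @param eps,min_pts Detection parameters when `clusters = "detect"`.
#' @param unit,randomize Passed to [normalized_overlap_ratio()].
#' @return Data frame from [coloc_results_table()].
#' @export
coloc_cohort <- function(nuclei, n_sim = 20, seed = 1,
                         clusters = c("truth", "detect"),
                         eps = 75, min_pts = 5,
                         unit = "pairs", randomize = "both") {
  clusters <- match.arg(clusters)
  results <- lapply(nuclei, function(nuc) {
    if (clusters == "truth") {
      a <- truth_cluster_set(nuc, "A")
      b <- truth_cluster_set(nuc, "B")
    } else {
      locs <- nuc$locs
      chans <- unique(locs$channel)
      la <- locs[locs$channel == chans[1L], , drop = FALSE]
      lb <- locs[locs$channel == chans[2L], , drop = FALSE]
      class(la) <- class(lb) <- c("localization_table", "data.frame")
      a <- detect_clusters(la, nuc$roi, eps = eps, min_pts = min_pts)
      b <- detect_clusters(lb, nuc$roi, eps = eps, min_pts = min_pts)
    }
    normalized_overlap_ratio(
      a, b, nuc$roi, n_sim = n_sim,
      seed = nucleus_seed(seed, nuc$roi$nucleus_id),
      unit = unit, randomize = randomize
    )
  })
  coloc_results_table(results)
}
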