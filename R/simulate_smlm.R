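# Synthetic SMLM nuclei: clustered two-channel point patterns inside a
# nucleus ROI, with a controllable fraction of colocalized clusters and
# uniform background localizations. The generator works at the cluster
# level (shared centroids plus jitter), because clusters are the unit the
# colocalization statistic randomizes and counts.

#' Simulation settings for a two-channel SMLM nucleus
#'
#' Defaults describe the reference condition used throughout the test
#' suite: a 10 x 10 um square nucleus with 40 clusters per channel of fixed
#' 100 nm radius, independent channels (`coloc_fraction = 0`), ~30
#' localizations per cluster and a light uniform background.
#'
#' @param roi `nucleus_roi` to populate (default 10 x 10 um rectangle).
#' @param n_clusters_a,n_clusters_b Clusters per channel (default 40).
#' @param coloc_fraction Probability that a B cluster is seeded at a random
#'   A centroid (plus jitter) instead of an independent uniform position;
#'   in `[0, 1]`, default 0.
#' @param jitter_sd Gaussian jitter (nm, per axis) applied to colocalized B
#'   centroids (default 50).
#' @param radius_mean,radius_sd Cluster effective-radius distribution in nm
#'   (default 100 +/- 0: fixed radius).
#' @param locs_per_cluster Mean localizations per cluster (Poisson,
#'   minimum 1; default 30).
#' @param background_density Uniform background localizations per um^2 per
#'   channel (default 2).
#' @return An `smlm_sim_spec` list.
#' @export
smlm_sim_spec <- function(roi = roi_rect(0, 0, 1e4, 1e4),
                          n_clusters_a = 40, n_clusters_b = 40,
                          coloc_fraction = 0, jitter_sd = 50,
                          radius_mean = 100, radius_sd = 0,
                          locs_per_cluster = 30, background_density = 2) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    format_error("spec error: coloc_fraction must be in [0, 1]")
  }
  if (background_density < 0 || locs_per_cluster < 0 ||
      radius_mean <= 0 || radius_sd < 0 || jitter_sd < 0) {
    format_error("spec error: densities, radii and jitter must be non-negative")
  }
  structure(
    list(roi = roi, n_clusters_a = n_clusters_a, n_clusters_b = n_clusters_b,
         coloc_fraction = coloc_fraction, jitter_sd = jitter_sd,
         radius_mean = radius_mean, radius_sd = radius_sd,
         locs_per_cluster = locs_per_cluster,
         background_density = background_density),
    class = "smlm_sim_spec"
  )
}

# truncated-normal radii: resample non-positive draws; sd = 0 -> constant
draw_radii <- function(n, mean, sd) {
  if (sd == 0 || n == 0L) {
    return(rep(mean, n))
  }
  r <- stats::rnorm(n, mean, sd)
  while (any(r <= 0)) {
    r[r <= 0] <- stats::rnorm(sum(r <= 0), mean, sd)
  }
  r
}

# Gaussian member offsets truncated at the cluster radius
draw_members <- function(n, radius) {
  if (n == 0L) {
    return(cbind(dx = numeric(0), dy = numeric(0)))
  }
  if (radius <= 0) {
    return(cbind(dx = rep(0, n), dy = rep(0, n)))
  }
  sd <- radius / 2
  dx <- stats::rnorm(n, 0, sd)
  dy <- stats::rnorm(n, 0, sd)
  for (it in 1:50) {
    out <- dx^2 + dy^2 > radius^2
    if (!any(out)) break
    dx[out] <- stats::rnorm(sum(out), 0, sd)
    dy[out] <- stats::rnorm(sum(out), 0, sd)
  }
  # after 50 rounds any stragglers are radially clipped (vanishingly rare)
  out <- dx^2 + dy^2 > radius^2
  if (any(out)) {
    f <- radius / sqrt(dx[out]^2 + dy[out]^2)
    dx[out] <- dx[out] * f
    dy[out] <- dy[out] * f
  }
  cbind(dx = dx, dy = dy)
}

# uniform points inside an ROI (rejection from bbox for mask/polygon)
sample_uniform_in_roi <- function(roi, n) {
  if (n == 0L) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  if (roi$type == "rect") {
    return(cbind(x = stats::runif(n, roi$xmin, roi$xmax),
                 y = stats::runif(n, roi$ymin, roi$ymax)))
  }
  if (roi$type == "disc") {
    rr <- roi$radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    return(cbind(x = roi$cx + rr * cos(th), y = roi$cy + rr * sin(th)))
  }
  bb <- roi_bbox(roi)
  out <- matrix(NA_real_, n, 2L)
  filled <- 0L
  while (filled < n) {
    m <- max(64L, 2L * (n - filled))
    x <- stats::runif(m, bb[1L], bb[3L])
    y <- stats::runif(m, bb[2L], bb[4L])
    ok <- which(roi_contains(roi, x, y))
    take <- ok[seq_len(min(length(ok), n - filled))]
    if (length(take)) {
      out[(filled + 1L):(filled + length(take)), ] <- cbind(x[take], y[take])
      filled <- filled + length(take)
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Simulate one two-channel SMLM nucleus
#'
#' Channel A cluster centroids are uniform over the ROI (eroded by each
#' cluster's radius so discs fit); each channel B cluster is, independently
#' with probability `coloc_fraction`, seeded at a randomly chosen A
#' centroid plus Gaussian jitter, otherwise placed uniformly. Member
#' localizations are Gaussian around the centroid truncated at the drawn
#' radius; uniform background points are appended. The ground truth records
#' which B clusters were seeded on A.
#'
#' @param spec An [smlm_sim_spec()].
#' @param nucleus_id Identifier (default `"n1"`).
#' @param seed Integer seed or `NULL`.
#' @return List: `locs` (`localization_table`, both channels `"A"`/`"B"`),
#'   `roi` (with this nucleus id), `truth` (list of data frames `a`, `b`
#'   with centroid, radius, n_loc and, for B, a `coloc` flag).
#' @export
simulate_smlm_nucleus <- function(spec, nucleus_id = "n1", seed = NULL) {
  stopifnot(inherits(spec, "smlm_sim_spec"))
  with_seed(seed, {
    roi <- spec$roi
    roi$nucleus_id <- nucleus_id

    ra <- draw_radii(spec$n_clusters_a, spec$radius_mean, spec$radius_sd)
    ca <- matrix(NA_real_, spec$n_clusters_a, 2L)
    for (r in unique(ra)) {
      sel <- which(ra == r)
      ca[sel, ] <- sample_admissible(roi, r, length(sel), what = "cluster")
    }

    rb <- draw_radii(spec$n_clusters_b, spec$radius_mean, spec$radius_sd)
    is_coloc <- stats::runif(spec$n_clusters_b) < spec$coloc_fraction
    cb <- matrix(NA_real_, spec$n_clusters_b, 2L)
    if (any(!is_coloc)) {
      sel <- which(!is_coloc)
      for (r in unique(rb[sel])) {
        ssel <- sel[rb[sel] == r]
        cb[ssel, ] <- sample_admissible(roi, r, length(ssel), what = "cluster")
      }
    }
    if (any(is_coloc)) {
      sel <- which(is_coloc)
      host <- sample.int(spec$n_clusters_a, length(sel), replace = TRUE)
      cb[sel, 1L] <- ca[host, 1L] + stats::rnorm(length(sel), 0, spec$jitter_sd)
      cb[sel, 2L] <- ca[host, 2L] + stats::rnorm(length(sel), 0, spec$jitter_sd)
    }

    emit_channel <- function(centres, radii) {
      n_loc <- pmax(1L, stats::rpois(nrow(centres), spec$locs_per_cluster))
      xs <- vector("list", nrow(centres))
      for (i in seq_len(nrow(centres))) {
        off <- draw_members(n_loc[i], radii[i])
        xs[[i]] <- cbind(centres[i, 1L] + off[, 1L], centres[i, 2L] + off[, 2L])
      }
      area_um2 <- roi_area(roi) / 1e6
      n_bg <- stats::rpois(1L, spec$background_density * area_um2)
      bg <- sample_uniform_in_roi(roi, n_bg)
      list(pts = rbind(do.call(rbind, xs), unname(bg)), n_loc = n_loc)
    }
    ea <- emit_channel(ca, ra)
    eb <- emit_channel(cb, rb)

    locs <- rbind(
      localization_table(nucleus_id, "A", ea$pts[, 1L], ea$pts[, 2L]),
      localization_table(nucleus_id, "B", eb$pts[, 1L], eb$pts[, 2L])
    )
    class(locs) <- c("localization_table", "data.frame")

    truth <- list(
      a = data.frame(
        cluster_id = sprintf("A%03d", seq_len(spec$n_clusters_a)),
        x = ca[, 1L], y = ca[, 2L], radius = ra, n_loc = ea$n_loc,
        stringsAsFactors = FALSE
      ),
      b = data.frame(
        cluster_id = sprintf("B%03d", seq_len(spec$n_clusters_b)),
        x = cb[, 1L], y = cb[, 2L], radius = rb, n_loc = eb$n_loc,
        coloc = is_coloc, stringsAsFactors = FALSE
      )
    )
    list(locs = locs, roi = roi, truth = truth)
  })
}

#' Ground-truth cluster set of a simulated nucleus
#'
#' @param nucleus A nucleus from [simulate_smlm_nucleus()].
#' @param channel `"A"` or `"B"`.
#' @return A `cluster_set` built from the simulator's ground truth.
#' @export
truth_cluster_set <- function(nucleus, channel = c("A", "B")) {
  channel <- match.arg(channel)
  tr <- if (channel == "A") nucleus$truth$a else nucleus$truth$b
  cluster_set(nucleus$roi$nucleus_id, channel,
              tr[, c("cluster_id", "x", "y", "radius", "n_loc")])
}

#' Simulate a cohort of SMLM nuclei
#'
#' Each nucleus gets a child seed derived from the root seed and its id via
#' [nucleus_seed()], so cohorts are reproducible and extendable without
#' perturbing existing nuclei.
#'
#' @param n_nuclei Number of nuclei.
#' @param spec An [smlm_sim_spec()] shared by all nuclei.
#' @param seed Root seed.
#' @param ids Nucleus identifiers (default `nucleus_001`, ...).
#' @return List of nuclei (see [simulate_smlm_nucleus()]).
#' @export
simulate_smlm_cohort <- function(n_nuclei, spec = smlm_sim_spec(), seed = 1,
                                 ids = sprintf("nucleus_%03d", seq_len(n_nuclei))) {
  stopifnot(n_nuclei >= 1, length(ids) == n_nuclei)
  lapply(ids, function(id) {
    simulate_smlm_nucleus(spec, nucleus_id = id, seed = nucleus_seed(seed, id))
  })
}
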