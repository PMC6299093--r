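# Synthetic DRIP-style experiment: negative-binomial bin counts for a cut
# and an uncut condition on one simulated chromosome, with enrichment in
# the cut condition rising with distance from each cut site according to a
# piecewise-linear amplitude profile.

#' Enrichment amplitude profile around a cut site
#'
#' Fold-enrichment as a function of absolute distance from the cut. The
#' default `"triangular"` shape is 1 at the cut, rises linearly to
#' `peak_fold` at `peak_distance`, declines linearly back to 1 at
#' `max_distance` and is 1 beyond; `"flat"` is `peak_fold` everywhere
#' within `max_distance` (useful for calibration checks).
#'
#' @param d Absolute distance(s) from the cut in bp.
#' @param peak_fold Fold enrichment at the peak (default 3; 1 gives a flat
#'   null profile).
#' @param peak_distance Distance of the peak in bp (default 1500).
#' @param max_distance Distance at which enrichment has decayed back to 1
#'   (default 3000).
#' @param shape `"triangular"` (default) or `"flat"`.
#' @return Fold-enrichment values `>= 1`.
#' @export
amplitude_profile <- function(d, peak_fold = 3, peak_distance = 1500,
                              max_distance = 3000,
                              shape = c("triangular", "flat")) {
  stopifnot(peak_fold >= 1, peak_distance > 0, max_distance > peak_distance)
  shape <- match.arg(shape)
  a <- rep(1, length(d))
  if (shape == "flat") {
    a[d < max_distance] <- peak_fold
    return(a)
  }
  up <- d <= peak_distance
  a[up] <- 1 + (peak_fold - 1) * d[up] / peak_distance
  down <- d > peak_distance & d < max_distance
  a[down] <- peak_fold - (peak_fold - 1) *
    (d[down] - peak_distance) / (max_distance - peak_distance)
  a
}

#' Simulation settings for a DRIP-style experiment
#'
#' Defaults give 50 well-separated cut sites on a 3 Mb chromosome, 50-bp
#' bins, enrichment peaking 3-fold at 1.5 kb and decayed by 3 kb, a
#' baseline of 100 reads per bin (a deeply sequenced library) and
#' negative-binomial dispersion `size = 20` (mildly overdispersed relative
#' to Poisson). At these settings the per-bin log2 ratio noise is ~0.5,
#' so a 50-site cohort resolves per-window medians to ~0.02.
#'
#' @param chrom_length Chromosome length in bp (default 3e6).
#' @param chrom Chromosome name (default `"chrSim"`).
#' @param bin_width Bin width in bp (default 50).
#' @param n_sites Number of cut sites (default 50).
#' @param frac_genic Probability a site is genic (default 0.5).
#' @param peak_fold,peak_distance,max_distance,shape Amplitude profile,
#'   see [amplitude_profile()].
#' @param baseline Mean uncut count per bin (default 100).
#' @param dispersion Negative-binomial size parameter (default 20;
#'   `Inf` gives Poisson counts).
#' @param depth_factor_cut,depth_factor_uncut Library-depth multipliers on
#'   the expected counts (default 1).
#' @return A `drip_sim_spec` list.
#' @export
drip_sim_spec <- function(chrom_length = 3e6, chrom = "chrSim",
                          bin_width = 50, n_sites = 50, frac_genic = 0.5,
                          peak_fold = 3, peak_distance = 1500,
                          max_distance = 3000, shape = "triangular",
                          baseline = 100, dispersion = 20,
                          depth_factor_cut = 1, depth_factor_uncut = 1) {
  if (dispersion <= 0) {
    format_error("spec error: dispersion must be > 0")
  }
  if (baseline <= 0 || chrom_length < 2 * max_distance * n_sites) {
    format_error("spec error: chromosome too short for the requested sites")
  }
  structure(
    list(chrom_length = chrom_length, chrom = chrom, bin_width = bin_width,
         n_sites = n_sites, frac_genic = frac_genic, peak_fold = peak_fold,
         peak_distance = peak_distance, max_distance = max_distance,
         shape = match.arg(shape, c("triangular", "flat")),
         baseline = baseline, dispersion = dispersion,
         depth_factor_cut = depth_factor_cut,
         depth_factor_uncut = depth_factor_uncut),
    class = "drip_sim_spec"
  )
}

# n sorted positions in [margin, L - margin], uniform conditional on all
# gaps >= min_sep (exact via the spacing construction, no rejection)
sample_separated_positions <- function(n, L, margin, min_sep) {
  free <- (L - 2 * margin) - (n - 1) * min_sep
  if (free <= 0) {
    format_error("spec error: cut sites cannot be separated by ", min_sep, " bp")
  }
  u <- sort(stats::runif(n, 0, free))
  round(margin + u + (seq_len(n) - 1) * min_sep)
}

#' Simulate a cut/uncut DRIP-style experiment
#'
#' Uncut bin counts are NB(`baseline`, `dispersion`); cut bin counts are
#' NB(`baseline * a(d)`, `dispersion`) where `d` is the bin centre's
#' distance to the nearest cut site and `a` the amplitude profile. Site
#' positions keep a minimum separation of `2 * max_distance` so per-site
#' footprints never overlap; cleavage scores are drawn uniformly (distinct
#' with probability one) so a known top-k subset exists; genic flags are
#' Bernoulli(`frac_genic`).
#'
#' Alongside the tracks, the nominal library sizes
#' `n_bins * baseline * depth_factor` are returned. These model the
#' genome-wide sequencing depth the counts were drawn at: on a real genome
#' the DSB-proximal enriched fraction is a negligible share of the library,
#' so RPKM normalization should use these rather than the realized sum of
#' the short simulated chromosome (whose enrichment would otherwise be
#' absorbed into the scaling and bias background bins downward).
#'
#' @param spec A [drip_sim_spec()].
#' @param seed Integer seed or `NULL`.
#' @return List: `cut`, `uncut` (count `bin_track`s), `sites`
#'   (`cut_site_table`), `library_size_cut`, `library_size_uncut`
#'   (nominal depths for RPKM), `truth` (data frame per bin: `start`,
#'   `distance` to nearest site (`NA` outside all footprints), `amplitude`,
#'   `expected_log2 = log2(amplitude)` adjusted for depth factors).
#' @export
simulate_drip_experiment <- function(spec = drip_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "drip_sim_spec"))
  with_seed(seed, {
    starts <- seq(0, spec$chrom_length - 1, by = spec$bin_width)
    ends <- pmin(starts + spec$bin_width, spec$chrom_length)
    mid <- (starts + ends) / 2

    pos <- sample_separated_positions(
      spec$n_sites, spec$chrom_length,
      margin = spec$max_distance, min_sep = 2 * spec$max_distance
    )
    sites <- cut_site_table(
      chrom = spec$chrom, position = pos,
      cleavage_score = stats::runif(spec$n_sites),
      genic = stats::runif(spec$n_sites) < spec$frac_genic
    )

    # distance of each bin centre to the nearest cut site
    idx <- findInterval(mid, pos)
    d_left <- ifelse(idx >= 1, mid - pos[pmax(idx, 1L)], Inf)
    d_right <- ifelse(idx < length(pos), pos[pmin(idx + 1L, length(pos))] - mid, Inf)
    d <- pmin(d_left, d_right)

    a <- amplitude_profile(d, spec$peak_fold, spec$peak_distance,
                           spec$max_distance, shape = spec$shape)
    mu_uncut <- spec$baseline * spec$depth_factor_uncut
    mu_cut <- spec$baseline * a * spec$depth_factor_cut
    draw <- function(mu) {
      if (is.infinite(spec$dispersion)) {
        stats::rpois(length(starts), mu)
      } else {
        stats::rnbinom(length(starts), mu = mu, size = spec$dispersion)
      }
    }
    uncut <- bin_track(spec$chrom, starts, ends, draw(rep(mu_uncut, length(starts))),
                       bin_width = spec$bin_width)
    cut <- bin_track(spec$chrom, starts, ends, draw(mu_cut),
                     bin_width = spec$bin_width)
    truth <- data.frame(
      start = starts,
      distance = ifelse(is.finite(d) & d < spec$max_distance, d, NA_real_),
      amplitude = a,
      expected_log2 = log2(a * spec$depth_factor_cut / spec$depth_factor_uncut)
    )
    list(cut = cut, uncut = uncut, sites = sites,
         library_size_cut = length(starts) * mu_uncut * spec$depth_factor_cut /
           spec$depth_factor_uncut,
         library_size_uncut = length(starts) * mu_uncut,
         truth = truth)
  })
}

#' Scramble cut-site positions away from real sites
#'
#' Control for the enrichment profile: returns a site table of the same
#' size whose positions are re-drawn uniformly (same separation rule) and
#' rejected until every scrambled site is at least `max_distance` away
#' from all original sites, so scrambled footprints sample only baseline
#' signal.
#'
#' @param sites Original `cut_site_table`.
#' @param spec The [drip_sim_spec()] the sites came from.
#' @param seed Integer seed or `NULL`.
#' @param max_attempts Resampling cap (default 1000).
#' @return A `cut_site_table` with scrambled positions.
#' @export
scramble_sites <- function(sites, spec, seed = NULL, max_attempts = 1000) {
  stopifnot(inherits(sites, "cut_site_table"), inherits(spec, "drip_sim_spec"))
  with_seed(seed, {
    for (i in seq_len(max_attempts)) {
      pos <- sample_separated_positions(
        nrow(sites), spec$chrom_length,
        margin = spec$max_distance, min_sep = 2 * spec$max_distance
      )
      d_min <- vapply(pos, function(p) min(abs(p - sites$position)), numeric(1))
      if (all(d_min >= spec$max_distance)) {
        out <- sites
        out$position <- pos
        return(out)
      }
    }
    format_error("could not scramble sites away from the originals after ",
                 max_attempts, " attempts")
  })
}
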