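# Pipeline driver: wires the simulation and analysis stages together from
# one structured config (R list or YAML file), writes TSV/JSON artifacts
# and a run manifest into an output directory.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_error <- function(key, why) {
  format_error(sprintf("config error at '%s': %s", key, why))
}

check_num <- function(cfg, section, key, lower = -Inf, allow_null = TRUE) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) {
    if (allow_null) return(invisible(NULL))
    config_error(paste(section, key, sep = "."), "missing")
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lower) {
    config_error(paste(section, key, sep = "."),
                 sprintf("must be a finite number >= %g", lower))
  }
  invisible(NULL)
}

#' Export dot-plot data from colocalization results
#'
#' Long-format table mirroring per-nucleus dot-plot panels: one row per
#' valid (non-degenerate) nucleus with its normalized ratio and group
#' label. Excluded nuclei are counted in attribute `n_excluded`.
#'
#' @param results Data frame from [coloc_results_table()] /
#'   [coloc_cohort()].
#' @param groups Group label per row (recycled; default `"all"`).
#' @return Data frame: `value`, `group`, `nucleus_id`.
#' @export
export_dotplot_data <- function(results, groups = "all") {
  stopifnot(nrow(results) > 0L)
  groups <- rep_len(as.character(groups), nrow(results))
  keep <- results$flag == "ok"
  out <- data.frame(
    value = results$ratio[keep],
    group = groups[keep],
    nucleus_id = results$nucleus_id[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Run the configured pipeline stages
#'
#' Accepts a structured config (nested R list, or path to an equivalent
#' YAML file) and executes the requested stages in dependency order,
#' writing all outputs plus a JSON run manifest into `out_dir`. Recognized
#' sections:
#'
#' * `seed`: root seed for the whole run (default 1).
#' * `simulate_smlm`: `n_nuclei` plus any [smlm_sim_spec()] field
#'   (`n_clusters_a`, `coloc_fraction`, ...). Writes `smlm_localizations.csv`.
#' * `coloc`: `n_sim` (default 20), `eps` (default 75), `min_pts` (default
#'   5), `clusters` (`"truth"`/`"detect"`), `group` label. Requires
#'   `simulate_smlm`. Writes `coloc_results.tsv` and `coloc_dotplot.tsv`.
#' * `simulate_drip`: any [drip_sim_spec()] field. Writes
#'   `drip_cut.bedgraph`, `drip_uncut.bedgraph`, `drip_sites.bed`.
#' * `drip_profile`: `top_k` (default 50), `min_overlap_frac` (default
#'   0.9), `pseudocount` (default 1), optional input paths `cut`, `uncut`,
#'   `sites` (otherwise the simulated tracks are used). Writes
#'   `drip_per_site.tsv`, `drip_summary.tsv`, `drip_long.tsv`.
#' * `qpcr`: `true_folds` (named list), `cv`, `n_replicates`,
#'   `input_fraction`. Writes `qpcr_table.tsv`, `qpcr_folds.tsv`.
#'
#' Reruns with the same config and seed produce byte-identical TSV/JSON
#' outputs; the manifest omits wall-clock timestamps by default for that
#' reason (`include_timestamp = TRUE` restores them).
#'
#' @param config Nested list or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @param include_timestamp Record a timestamp in the manifest? Default
#'   `FALSE` to keep manifests reproducible.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, include_timestamp = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      format_error("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    config_error("(root)", "config must be a list or a YAML file path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    config_error("seed", "must be a single finite number")
  }
  check_num(config, "coloc", "eps", lower = 1e-9)
  check_num(config, "coloc", "min_pts", lower = 1)
  check_num(config, "coloc", "n_sim", lower = 1)
  check_num(config, "drip_profile", "top_k", lower = 1)
  check_num(config, "drip_profile", "pseudocount", lower = 1e-12)
  check_num(config, "qpcr", "cv", lower = 0)

  results <- list()
  outputs <- character(0)
  counts <- list()

  if (!is.null(config$simulate_smlm)) {
    sc <- config$simulate_smlm
    n_nuclei <- sc$n_nuclei %||% 10L
    spec_args <- sc[setdiff(names(sc), "n_nuclei")]
    spec <- do.call(smlm_sim_spec, spec_args)
    nuclei <- simulate_smlm_cohort(n_nuclei, spec, seed = seed)
    results$smlm <- nuclei
    all_locs <- do.call(rbind, lapply(nuclei, `[[`, "locs"))
    class(all_locs) <- c("localization_table", "data.frame")
    p <- file.path(out_dir, "smlm_localizations.csv")
    write_localizations(all_locs, p,
                        loc_dialect(channel = "channel", nucleus = "nucleus_id"))
    outputs <- c(outputs, p)
  }

  if (!is.null(config$coloc)) {
    if (is.null(results$smlm)) {
      config_error("coloc", "requires a simulate_smlm section")
    }
    cc <- config$coloc
    tab <- coloc_cohort(
      results$smlm,
      n_sim = cc$n_sim %||% 20L,
      seed = seed,
      clusters = cc$clusters %||% "truth",
      eps = cc$eps %||% 75,
      min_pts = cc$min_pts %||% 5
    )
    results$coloc <- tab
    p1 <- file.path(out_dir, "coloc_results.tsv")
    write_tsv(tab, p1)
    dot <- export_dotplot_data(tab, groups = cc$group %||% "all")
    p2 <- file.path(out_dir, "coloc_dotplot.tsv")
    write_tsv(dot, p2)
    outputs <- c(outputs, p1, p2)
    counts$coloc_degenerate <- attr(dot, "n_excluded")
  }

  if (!is.null(config$simulate_drip)) {
    spec <- do.call(drip_sim_spec, config$simulate_drip)
    sim <- simulate_drip_experiment(spec, seed = seed)
    results$drip_sim <- sim
    pc <- file.path(out_dir, "drip_cut.bedgraph")
    pu <- file.path(out_dir, "drip_uncut.bedgraph")
    ps <- file.path(out_dir, "drip_sites.bed")
    write_bedgraph(sim$cut, pc)
    write_bedgraph(sim$uncut, pu)
    write_cut_sites(sim$sites, ps)
    outputs <- c(outputs, pc, pu, ps)
  }

  if (!is.null(config$drip_profile)) {
    dc <- config$drip_profile
    if (!is.null(dc$cut)) {
      cut <- read_bedgraph(dc$cut)
      uncut <- read_bedgraph(dc$uncut)
      sites <- read_cut_sites(dc$sites)
    } else if (!is.null(results$drip_sim)) {
      cut <- results$drip_sim$cut
      uncut <- results$drip_sim$uncut
      sites <- results$drip_sim$sites
    } else {
      config_error("drip_profile", "needs input paths or a simulate_drip section")
    }
    prof <- drip_profile(
      cut, uncut, sites,
      top_k = dc$top_k %||% 50,
      min_overlap_frac = dc$min_overlap_frac %||% 0.9,
      pseudocount = dc$pseudocount %||% 1
    )
    results$drip <- prof
    p1 <- file.path(out_dir, "drip_per_site.tsv")
    p2 <- file.path(out_dir, "drip_summary.tsv")
    p3 <- file.path(out_dir, "drip_long.tsv")
    write_tsv(prof$per_site, p1)
    write_tsv(prof$summary, p2)
    long <- prof$per_site[, c("site_id", "interval", "mean_log2")]
    names(long) <- c("site_id", "group", "value")
    write_tsv(long, p3)
    outputs <- c(outputs, p1, p2, p3)
    counts$drip_omitted_pairs <- attr(prof$per_site, "n_omitted")
  }

  if (!is.null(config$qpcr)) {
    qc <- config$qpcr
    if (is.null(qc$true_folds)) {
      config_error("qpcr.true_folds", "missing")
    }
    tab <- simulate_qpcr_table(
      unlist(qc$true_folds),
      cv = qc$cv %||% 0.2,
      n_replicates = qc$n_replicates %||% 3L,
      input_fraction = qc$input_fraction %||% 0.01,
      seed = seed
    )
    folds <- fold_induction_table(tab)
    results$qpcr <- folds
    p1 <- file.path(out_dir, "qpcr_table.tsv")
    p2 <- file.path(out_dir, "qpcr_folds.tsv")
    write_tsv(tab, p1)
    write_tsv(folds$summary, p2)
    outputs <- c(outputs, p1, p2)
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("dsbquant")),
    seed = seed,
    params = config,
    outputs = basename(outputs),
    output_md5 = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)
    )),
    counts = counts
  )
  if (include_timestamp) {
    manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
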