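# Synthetic qPCR tables: replicated IP/input quantities for cut and uncut
# conditions with log-normal measurement noise on the IP recovery.

#' Simulate a long-format qPCR measurement table
#'
#' For each region with a true cut/uncut fold induction, generates
#' `n_replicates` paired measurements of IP and input quantities in both
#' conditions. Measurement noise is multiplicative log-normal with mean 1
#' and coefficient of variation `cv`, applied to the IP quantities; the
#' input quantities are taken as exact, since inputs are dilutions of the
#' same chromatin pool and their variability is dominated by the IP
#' recovery step. Under this model the per-replicate fold estimator is
#' unbiased up to O(cv^2).
#'
#' @param true_folds Named numeric vector: true fold induction per region.
#' @param cv Coefficient of variation of the IP noise (`>= 0`, default
#'   0.2).
#' @param n_replicates Replicates per region (default 3).
#' @param uncut_percent_input True uncut percent-input level (default 0.5,
#'   i.e. 0.5% of input).
#' @param input_fraction Fraction of chromatin used as input (default
#'   0.01).
#' @param seed Integer seed or `NULL`.
#' @return Long-format data frame with columns `region`, `condition`
#'   (`"cut"`/`"uncut"`), `fraction` (`"IP"`/`"input"`), `replicate`,
#'   `quantity`, `input_fraction`, ready for [fold_induction_table()].
#' @export
simulate_qpcr_table <- function(true_folds, cv = 0.2, n_replicates = 3,
                                uncut_percent_input = 0.5,
                                input_fraction = 0.01, seed = NULL) {
  if (cv < 0) {
    format_error("spec error: cv must be >= 0")
  }
  stopifnot(n_replicates >= 1, length(true_folds) >= 1)
  if (is.null(names(true_folds))) {
    names(true_folds) <- sprintf("region_%d", seq_along(true_folds))
  }
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) {
    if (cv == 0) rep(1, n) else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    input_q <- 1 # arbitrary linear units; ratios are what matter
    rows <- list()
    for (rg in names(true_folds)) {
      for (cond in c("uncut", "cut")) {
        pi_true <- uncut_percent_input *
          if (cond == "cut") true_folds[[rg]] else 1
        ip_true <- pi_true / 100 * input_q / input_fraction
        ip <- ip_true * noise(n_replicates)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, condition = cond,
          fraction = rep(c("IP", "input"), each = n_replicates),
          replicate = rep(seq_len(n_replicates), times = 2L),
          quantity = c(ip, rep(input_q, n_replicates)),
          input_fraction = input_fraction,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
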