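# qPCR arithmetic: percent-input normalization for DRIP-/ChIP-qPCR,
# cut/uncut fold induction, and normalizer-relative expression (delta-delta
# Cq) for RT-qPCR panels.

#' Percent input
#'
#' `100 * ip / (input / input_fraction)`: the IP signal as a percentage of
#' the dilution-corrected input chromatin signal.
#'
#' @param ip IP-fraction quantity (linear scale).
#' @param input Input-fraction quantity (linear scale); values `<= 0` yield
#'   `NA` with a warning.
#' @param input_fraction Fraction of chromatin used as input, in `(0, 1]`
#'   (e.g. 0.01 for a 1% input).
#' @return Percentage(s); vectorized.
#' @export
percent_input <- function(ip, input, input_fraction) {
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    format_error("input_fraction must be in (0, 1]")
  }
  if (any(ip < 0, na.rm = TRUE)) {
    format_error("ip quantities must be >= 0")
  }
  bad <- !is.na(input) & input <= 0
  if (any(bad)) {
    warning(sprintf("percent_input undefined for %d measurement(s) with input <= 0",
                    sum(bad)), call. = FALSE)
  }
  out <- 100 * ip / (input / input_fraction)
  out[bad] <- NA_real_
  out
}

#' Convert Cq values to relative linear quantities
#'
#' `quantity = efficiency^(-cq)`, an arbitrary-scale abundance that cancels
#' in ratios.
#'
#' @param cq Cycle-of-quantification values.
#' @param efficiency Amplification efficiency in fold per cycle,
#'   `> 1` (default 2, perfect doubling).
#' @return Relative quantities.
#' @export
cq_to_quantity <- function(cq, efficiency = 2) {
  if (efficiency <= 1) {
    format_error("efficiency must be > 1 (fold per cycle)")
  }
  efficiency^(-cq)
}

#' Percent input from Cq values
#'
#' Equivalent to [percent_input()] after [cq_to_quantity()]:
#' `100 * efficiency^(input_cq - ip_cq) * input_fraction`.
#'
#' @param ip_cq,input_cq Cq of the IP and input fractions.
#' @param input_fraction Fraction of chromatin used as input.
#' @param efficiency Amplification efficiency (default 2).
#' @return Percentage(s).
#' @export
percent_input_cq <- function(ip_cq, input_cq, input_fraction, efficiency = 2) {
  percent_input(cq_to_quantity(ip_cq, efficiency),
                cq_to_quantity(input_cq, efficiency),
                input_fraction)
}

#' Fold induction of cut over uncut
#'
#' @param cut_pi,uncut_pi Percent-input values of the cut and uncut
#'   conditions; `uncut_pi <= 0` yields `NA` with a warning.
#' @return Ratio(s) `cut_pi / uncut_pi`.
#' @export
fold_induction <- function(cut_pi, uncut_pi) {
  bad <- !is.na(uncut_pi) & uncut_pi <= 0
  if (any(bad)) {
    warning(sprintf("fold_induction undefined for %d pair(s) with uncut <= 0",
                    sum(bad)), call. = FALSE)
  }
  out <- cut_pi / uncut_pi
  out[bad] <- NA_real_
  out
}

#' Normalizer-relative expression (delta-delta Cq)
#'
#' `efficiency^(-ddCq)` with
#' `ddCq = (target_cq - norm_cq) - (ref_target_cq - ref_norm_cq)`, the
#' standard relative-expression convention with a normalizer transcript
#' (e.g. 7SK, 47S or RPPO) and a reference sample.
#'
#' @param target_cq,norm_cq Cq of target and normalizer in the sample.
#' @param ref_target_cq,ref_norm_cq Cq of target and normalizer in the
#'   reference sample.
#' @param efficiency Amplification efficiency (default 2).
#' @return Relative quantity; 1 when sample and reference are identical.
#' @export
relative_expression <- function(target_cq, norm_cq, ref_target_cq,
                                ref_norm_cq, efficiency = 2) {
  if (efficiency <= 1) {
    format_error("efficiency must be > 1 (fold per cycle)")
  }
  ddcq <- (target_cq - norm_cq) - (ref_target_cq - ref_norm_cq)
  efficiency^(-ddcq)
}

#' Per-replicate fold inductions and their summary
#'
#' Takes a long-format table of qPCR measurements with columns `region`,
#' `condition` (`"cut"`/`"uncut"`), `fraction` (`"IP"`/`"input"`),
#' `replicate`, `quantity`, `input_fraction`, computes percent input per
#' (region, condition, replicate), then the fold induction per replicate,
#' and finally mean +/- s.e.m. across replicates per region. Folds are
#' computed per replicate and then averaged (never as a ratio of means), so
#' the s.e.m. reflects between-experiment variability.
#'
#' @param table Long-format data frame as above.
#' @return List: `per_replicate` (region, replicate, cut_pi, uncut_pi,
#'   fold) and `summary` (region, n, mean_fold, sem; `sem` is `NA` with a
#'   warning when n < 2).
#' @export
fold_induction_table <- function(table) {
  needed <- c("region", "condition", "fraction", "replicate", "quantity",
              "input_fraction")
  if (!all(needed %in% names(table))) {
    format_error("qPCR table needs columns: ", paste(needed, collapse = ", "))
  }
  pi_of <- function(region, condition, replicate) {
    sel <- table$region == region & table$condition == condition &
      table$replicate == replicate
    ip <- table$quantity[sel & table$fraction == "IP"]
    inp <- table$quantity[sel & table$fraction == "input"]
    fr <- table$input_fraction[sel][1L]
    if (length(ip) != 1L || length(inp) != 1L) {
      format_error(sprintf(
        "expected one IP and one input quantity for %s/%s replicate %s",
        region, condition, replicate
      ))
    }
    percent_input(ip, inp, fr)
  }
  combos <- unique(table[, c("region", "replicate")])
  per <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    rg <- combos$region[i]; rp <- combos$replicate[i]
    cut_pi <- pi_of(rg, "cut", rp)
    uncut_pi <- pi_of(rg, "uncut", rp)
    data.frame(region = rg, replicate = rp, cut_pi = cut_pi,
               uncut_pi = uncut_pi, fold = fold_induction(cut_pi, uncut_pi),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(per, per$region), function(d) {
    f <- d$fold[!is.na(d$fold)]
    n <- length(f)
    if (n < 2L) {
      warning(sprintf("s.e.m. undefined for region '%s' (n = %d)",
                      d$region[1L], n), call. = FALSE)
    }
    data.frame(region = d$region[1L], n = n, mean_fold = mean(f),
               sem = if (n >= 2L) stats::sd(f) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ)
}
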