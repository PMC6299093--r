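# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so that seeded operations never perturb the global
#' random stream. With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-nucleus child seed from a root seed
#'
#' Stable string hash (multiplicative, modulo 2^31 - 1) of the nucleus id,
#' combined with the root seed and then scrambled through three Lehmer
#' (MINSTD) steps. Adding or removing a nucleus from a cohort therefore
#' never changes any other nucleus's random stream, and ids or roots that
#' differ by small amounts still map to well-separated seeds (R's
#' Mersenne-Twister seeding fills its state from an LCG, so *adjacent*
#' integer seeds can yield weakly correlated streams; the scrambling
#' avoids handing it adjacent seeds in the first place).
#'
#' @param root_seed Integer root seed for the run.
#' @param nucleus_id Identifier (coerced to character).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' nucleus_seed(1L, "nucleus_007")
nucleus_seed <- function(root_seed, nucleus_id) {
  stopifnot(length(root_seed) == 1L, is.finite(root_seed))
  m <- 2147483647 # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- 17
  for (b in utf8ToInt(as.character(nucleus_id))) {
    h <- (h * 31 + b) %% m
  }
  x <- (h + as.numeric(root_seed) %% m) %% (m - 1) + 1
  for (i in 1:3) {
    x <- (x * 48271) %% m # MINSTD step; 48271 * 2^31 < 2^53 stays exact
  }
  as.integer(x)
}

# stop() with a consistent prefix used for user-facing format errors
format_error <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
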