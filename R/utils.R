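#' @importFrom stats rbinom rexp rlnorm rpois runif setNames pbinom cutree
#'   hclust as.dist cmdscale dist chisq.test pchisq ks.test
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; printed tables in this field use
#' conventional half-up rounding, so percentages go through this helper.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never clobbers the
#' caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-name substream seed, kept under 2^31
derive_seed <- function(base_seed, name) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(base_seed) * 7919 + h) %% .Machine$integer.max)
}
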