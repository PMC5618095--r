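#' @importFrom rlang abort warn .data %||%
#' @importFrom stats rnorm qnorm pnorm pt sd var aov anova coef lm predict quantile
#' @importFrom utils head tail
#' @importFrom stats fitted median
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Derive a reproducible substream seed from a global seed and a stage label,
# kept inside the 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL leaves the current stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "caffval_invalid_argument")
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "caffval_invalid_argument")
  }
  invisible(x)
}
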