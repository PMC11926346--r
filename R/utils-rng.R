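#' @keywords internal
"_PACKAGE"

#' @useDynLib reservoirMC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbeta quantile sd cor lm resid coef pt
#'   p.adjust cor.test predict dist
#' @importFrom utils read.table write.table combn head
NULL

# Deterministic substream seeds. Mixes an arbitrary number of integer or
# character keys into a seed in [0, 2^31 - 2] using multiply-and-add over
# doubles (all intermediates stay below 2^53, so the arithmetic is exact).
substream_seed <- function(...) {
  keys <- list(...)
  h <- 104729
  for (k in keys) {
    if (is.character(k)) {
      k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) %% 2147483647
    }
    for (v in as.numeric(k)) {
      h <- (h * 48271 + (v %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
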