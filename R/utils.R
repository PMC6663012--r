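#' @import methods
#' @importFrom stats median pf plogis pnorm rnorm runif rlnorm rbinom p.adjust
#'   quantile rgamma setNames
#' @importFrom utils head write.table read.table packageVersion
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based split of one master seed into independent sub-stream seeds,
# kept below 2^31 so they remain valid R integers.
deriveSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + 1103515245 * counter) %% 2147483587) + 1L
}

# I/L are isobaric and indistinguishable by MS; collapse both to 'J' so that
# string equality/containment tests respect the equivalence.
ilCollapseInternal <- function(x) chartr("IL", "JJ", x)

roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
}
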