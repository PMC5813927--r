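#' @useDynLib phenotext, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rgeom rnorm runif pchisq fisher.test predict
#' @importFrom utils head modifyList
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable binary NLL for targets in {0,1} given logits
# (vectorized): -log sigmoid(s) = softplus(-s).
nll_from_logit <- function(logit, target) {
  u <- ifelse(target == 1, -logit, logit)
  ifelse(u > 30, u, log1p(exp(u)))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package route
# through this so that equal seeds give byte-identical results.
with_seed <- function(seed, expr) {
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

# Derive a stream of child seeds from one seed, for stages that need
# independent randomness (kept below 2^30 so small offsets stay valid
# 32-bit seeds).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2L^30L - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
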