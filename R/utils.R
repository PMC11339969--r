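#' diffpes: diffusion models on toy potential energy surfaces
#'
#' Tools to study how denoising diffusion models over atomic point clouds
#' behave on a potential energy surface: synthetic toy molecules with analytic
#' energies and forces, a variance-preserving diffusion core with equivariant
#' and oracle denoisers, inference-trajectory metrics, force/ground-state
#' alignment statistics, Boltzmann-style chains with a step-to-temperature
#' calibration, and a relaxation-initialization benchmark.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's RNG stream. All stochastic operations in the package route their
#' randomness through this helper.
#'
#' @param seed integer seed (may be NULL for "use current stream").
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (seed, tag) to a new 32-bit-safe integer seed so that
#' every pipeline stage gets an independent but reproducible RNG stream.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2^31 - 1
  ## polynomial rolling hash (exact in doubles: intermediate < 2^53)
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h * 16807 + 12345) %% m)
}

## Project an n x 3 coordinate-like matrix onto the CoM-free subspace.
project_com <- function(x) {
  sweep(x, 2, colMeans(x))
}

## Random 3x3 rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Per-row L2 norms of an n x 3 matrix.
row_norms <- function(x) sqrt(rowSums(x^2))

## Flatten n x 3 coords to length-3n vector and back.
flatten_coords <- function(x) as.numeric(t(x))
unflatten_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)

## Effective sample size of a scalar chain from its autocorrelation
## (initial positive sequence truncation).
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos) > 0) ac <- ac[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}
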