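#' Construct a variance-preserving noise schedule
#'
#' Per-step signal and noise coefficients satisfying `alpha_n^2 + sigma_n^2
#' = 1` for all steps, with `alpha` monotonically decreasing from ~1 at `n = 0`
#' to ~0 at `n = N`. The default `"polynomial"` form is
#' `alpha_n^2 = (1 - 2s) (1 - (n/N)^2)^2 + s` with a small stability floor
#' `s`, so inference over `N` steps spans the full noise range without
#' division blow-ups when decoding.
#'
#' @param N total number of diffusion steps (>= 2); default 1000.
#' @param kind `"polynomial"` (default) or `"custom"` (supply `params$alpha`,
#'   a length `N + 1` decreasing vector for `n = 0..N`).
#' @param params list; `s` stability floor for the polynomial form,
#'   `alpha` for the custom form.
#' @return a `noise_schedule`: list with `N`, `alpha`, `sigma` (each length
#'   `N + 1`, index `n + 1` holds step `n`).
#' @export
make_schedule <- function(N = 1000, kind = c("polynomial", "custom"),
                          params = list()) {
  stopifnot(N >= 2)
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    s <- params$s %||% 1e-7
    n <- 0:N
    alpha2 <- (1 - 2 * s) * (1 - (n / N)^2)^2 + s
    alpha2[1] <- 1          # n = 0 is the clean latent: exact identity decode
    alpha <- sqrt(alpha2)
  } else {
    alpha <- params$alpha
    if (is.null(alpha) || length(alpha) != N + 1) {
      stop("custom schedule requires params$alpha of length N + 1")
    }
    if (any(diff(alpha) >= 0)) stop("user-supplied alpha must be strictly decreasing")
    if (any(alpha <= 0 | alpha >= 1 + 1e-12)) stop("alpha must lie in (0, 1]")
  }
  sigma <- sqrt(pmax(0, 1 - alpha^2))
  structure(list(N = as.integer(N), alpha = alpha, sigma = sigma, kind = kind),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule (%s): N=%d, alpha_1=%.4f, alpha_N=%.4f>\n",
              x$kind, x$N, sched_alpha(x, 1), sched_alpha(x, x$N)))
  invisible(x)
}

sched_alpha <- function(schedule, n) schedule$alpha[n + 1]
sched_sigma <- function(schedule, n) schedule$sigma[n + 1]
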