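#' Encode an atomic system as a clean diffusion latent
#'
#' Coordinates are translated so the centre of mass sits at the origin (the
#' diffusion process lives entirely in the CoM-free subspace); species become
#' scaled one-hot channel vectors.
#'
#' @param system an [atomic_system()].
#' @param alphabet species table defining the channel order.
#' @param h_scale one-hot scaling (default 0.25, balancing coordinate and
#'   channel loss terms).
#' @return a `clean_latent`: list with `x` (n x 3, CoM-free), `h` (n x C),
#'   `species`, `alphabet`, `h_scale`, `id`.
#' @export
encode_system <- function(system, alphabet = default_alphabet(),
                          h_scale = 0.25) {
  idx <- match(system$species, alphabet$species)
  if (anyNA(idx)) stop("unknown species label: ",
                       paste(unique(system$species[is.na(idx)]), collapse = ", "))
  C <- nrow(alphabet)
  h <- matrix(0, length(idx), C)
  h[cbind(seq_along(idx), idx)] <- h_scale
  structure(list(x = project_com(system$coords), h = h,
                 species = system$species, alphabet = alphabet,
                 h_scale = h_scale, id = system$id),
            class = "clean_latent")
}

#' Create a diffusion state at a given step
#'
#' @param zx n x 3 noisy coordinates (latent scale, CoM-free).
#' @param zh n x C noisy species channels.
#' @param n diffusion step.
#' @param meta list carried along (alphabet, h_scale, id).
#' @return a `diffusion_state`.
#' @keywords internal
diffusion_state <- function(zx, zh, n, meta) {
  structure(list(zx = zx, zh = zh, n = as.integer(n), meta = meta),
            class = "diffusion_state")
}

#' @export
print.diffusion_state <- function(x, ...) {
  cat(sprintf("<diffusion_state: n=%d, %d atoms, %d channels>\n",
              x$n, nrow(x$zx), ncol(x$zh)))
  invisible(x)
}

#' Apply forward noising at step n
#'
#' Returns `z = alpha_n * clean + sigma_n * eps` with the coordinate noise
#' projected onto the CoM-free subspace. The drawn noise is kept on the state
#' (attribute `eps`) for loss computation.
#'
#' @param latent a `clean_latent` from [encode_system()].
#' @param n diffusion step, `1 <= n <= N` (n = 0 returns the clean latent).
#' @param schedule a `noise_schedule`.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return a `diffusion_state` at step `n` with attribute `eps`
#'   (list `x`, `h`).
#' @export
forward_noise <- function(latent, n, schedule, seed = NULL) {
  stopifnot(n >= 0, n <= schedule$N)
  meta <- latent[c("alphabet", "h_scale", "id", "species")]
  if (n == 0) {
    st <- diffusion_state(latent$x, latent$h, 0, meta)
    attr(st, "eps") <- list(x = latent$x * 0, h = latent$h * 0)
    return(st)
  }
  with_seed(seed, {
    a <- sched_alpha(schedule, n)
    s <- sched_sigma(schedule, n)
    eps_x <- project_com(matrix(stats::rnorm(length(latent$x)),
                                nrow(latent$x), 3))
    eps_h <- matrix(stats::rnorm(length(latent$h)), nrow(latent$h),
                    ncol(latent$h))
    st <- diffusion_state(a * latent$x + s * eps_x, a * latent$h + s * eps_h,
                          n, meta)
    attr(st, "eps") <- list(x = eps_x, h = eps_h)
    st
  })
}

#' Decode a diffusion state into an atomic system
#'
#' Coordinates are rescaled by `1 / alpha_n` so that intermediate structures
#' along the diffusion path are well-defined at every step; below an
#' `alpha`-floor the coordinates are reported at latent scale with a
#' `latent_scale` flag instead of dividing by a vanishing signal coefficient.
#' Species are the argmax over channel values, ties broken deterministically
#' by the lowest channel index.
#'
#' @param state a `diffusion_state`.
#' @param schedule the `noise_schedule` used to produce it.
#' @param alpha_floor guard below which no rescaling is applied (default 0.05).
#' @return an [atomic_system()]; attribute `latent_scale` is TRUE when the
#'   guard was triggered.
#' @export
decode_state <- function(state, schedule, alpha_floor = 0.05) {
  a <- sched_alpha(schedule, state$n)
  guarded <- a < alpha_floor
  coords <- if (guarded) state$zx else state$zx / a
  ## argmax with lowest-index tie-break: max.col(..., "first")
  idx <- max.col(state$zh, ties.method = "first")
  species <- state$meta$alphabet$species[idx]
  sys <- atomic_system(species, coords, id = state$meta$id %||% "decoded")
  attr(sys, "latent_scale") <- guarded
  sys
}
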