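# Shared fixtures, built in code at test time.

# small cached bonded system + PES (5 atoms)
fixture_bonded <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      top <- sample_topology(5, seed = 3)
      pes <- build_pes(top, "bonded", seed = 3)
      cache <<- list(top = top, pes = pes,
                     system = atomic_system(top$species, pes$x_star,
                                            id = "fix5"))
    }
    cache
  }
})

# diatomic with a single harmonic bond, k = 100, r0 = 0.74
fixture_diatomic <- function(k_bond = 100) {
  top <- sample_topology(2, alphabet = data.frame(
    species = "A", max_degree = 1L, radius = 0.37,
    stringsAsFactors = FALSE), seed = 0)
  build_pes(top, "bonded", params = list(k_bond = k_bond), seed = 0)
}

# quadratic PES over a diatomic with an isotropic supplied Hessian
fixture_quadratic_iso <- function(kappa = 10, n_atoms = 2, seed = 4) {
  ab <- default_alphabet()
  top <- sample_topology(n_atoms, ab, seed = seed)
  build_pes(top, "quadratic",
            params = list(hessian = diag(kappa, 3 * n_atoms)), seed = seed)
}

# hand-built trajectory from a list of coordinate matrices + species matrix
fixture_trajectory <- function(coord_list, species_list, steps = NULL) {
  ab <- default_alphabet()
  nfr <- length(coord_list)
  if (is.null(steps)) steps <- seq(nfr - 1, 0)
  meta <- list(alphabet = ab, h_scale = 0.25, id = "fixture")
  states <- lapply(seq_len(nfr), function(i) {
    sp <- species_list[[i]]
    h <- matrix(0, length(sp), nrow(ab))
    h[cbind(seq_along(sp), match(sp, ab$species))] <- 0.25
    diffpes:::diffusion_state(project_com_fix(coord_list[[i]]), h,
                              steps[i], meta)
  })
  sched <- make_schedule(max(2, max(steps)))
  # bypass decode rescaling: build decoded frames directly at the raw scale
  decoded <- lapply(seq_len(nfr), function(i) {
    atomic_system(species_list[[i]], coord_list[[i]], id = "fixture")
  })
  deltas <- lapply(seq_len(nfr - 1), function(i) {
    coord_list[[i + 1]] - coord_list[[i]]
  })
  structure(list(states = states, decoded = decoded, deltas = deltas,
                 steps = as.integer(steps)),
            class = "diff_trajectory")
}

project_com_fix <- function(x) sweep(x, 2, colMeans(x))

expect_equal_mat <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
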