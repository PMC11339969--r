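test_that("sampled topologies are connected, valence-respecting and seeded", {
  # forced two-atom case: the single possible graph
  ab1 <- data.frame(species = "A", max_degree = 1L, radius = 0.37)
  top2 <- sample_topology(2, ab1, seed = 0)
  expect_equal(top2$bonds, matrix(c(1L, 2L), 1))

  # valence infeasibility: three max-degree-1 atoms cannot connect
  expect_error(sample_topology(3, ab1, seed = 1), "infeasible")

  # generic case: connectivity, degree caps, determinism
  ab <- default_alphabet()
  for (seed in c(7, 21, 99)) {
    top <- sample_topology(8, ab, seed = seed)
    expect_true(diffpes:::topology_connected(top))
    deg <- diffpes:::topology_degrees(top)
    maxdeg <- ab$max_degree[match(top$species, ab$species)]
    expect_true(all(deg <= maxdeg))
    expect_true(all(deg >= 1))
    expect_gte(nrow(top$bonds), 7)      # spanning tree over 8 atoms
    expect_false(any(top$bonds[, 1] == top$bonds[, 2]))
    expect_false(any(duplicated(top$bonds)))
  }
  expect_identical(sample_topology(8, ab, seed = 7),
                   sample_topology(8, ab, seed = 7))
})

test_that("analytic forces match central finite differences on both styles", {
  fd_forces <- function(pes, x, h = 1e-5) {
    num <- x * 0
    for (i in seq_len(nrow(x))) {
      for (k in 1:3) {
        xp <- x; xp[i, k] <- xp[i, k] + h
        xm <- x; xm[i, k] <- xm[i, k] - h
        num[i, k] <- -(pes_energy(pes, xp) - pes_energy(pes, xm)) / (2 * h)
      }
    }
    num
  }
  fix <- fixture_bonded()
  pes_q <- build_pes(fix$top, "quadratic", seed = 11)
  set.seed(42)
  for (rep in 1:20) {
    x <- fix$pes$x_star + matrix(rnorm(15, 0, 0.08), 5, 3)
    f <- pes_forces(fix$pes, x)
    expect_lt(max(abs(f - fd_forces(fix$pes, x))) / max(abs(f)), 1e-6)
    fq <- pes_forces(pes_q, x)
    expect_lt(max(abs(fq - fd_forces(pes_q, x))) / max(abs(fq)), 1e-6)
  }
})

test_that("simple closed-form PES values are exact", {
  # harmonic bond: energy zero and forces zero at r0; restoring force k*dr
  dia <- fixture_diatomic(k_bond = 100)
  r0 <- dia$ff$r0[1]
  at_r0 <- matrix(c(0, 0, 0, r0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(pes_energy(dia, at_r0), 0, tolerance = 1e-12)
  expect_lt(max(abs(pes_forces(dia, at_r0))), 1e-10)
  stretched <- matrix(c(0, 0, 0, r0 + 0.5, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(pes_energy(dia, stretched), 0.5 * 100 * 0.25, tolerance = 1e-12)
  f <- pes_forces(dia, stretched)
  expect_equal(f[2, 1], -100 * 0.5, tolerance = 1e-10)  # pulls atom 2 back

  # quadratic with identity Hessian: E = 0.5 ||d||^2
  pq <- fixture_quadratic_iso(kappa = 1, n_atoms = 2)
  d <- matrix(c(0.1, -0.2, 0.3, 0, 0.05, 0), 2, 3, byrow = TRUE)
  expect_equal(pes_energy(pq, pq$x_star + d), 0.5 * sum(d^2), tolerance = 1e-12)

  # supplied non-PSD Hessian is rejected
  ab <- default_alphabet()
  top2 <- sample_topology(2, ab, seed = 1)
  expect_error(build_pes(top2, "quadratic",
                         params = list(hessian = diag(c(-1, rep(1, 5))))),
               "PSD")
})

test_that("bonded energies are rigid-body invariant", {
  fix <- fixture_bonded()
  set.seed(5)
  x <- fix$pes$x_star + matrix(rnorm(15, 0, 0.1), 5, 3)
  e0 <- pes_energy(fix$pes, x)
  for (rep in 1:5) {
    r <- diffpes:::random_rotation()
    shift <- matrix(rnorm(3), 1)
    xt <- sweep(x %*% t(r), 2, shift, `+`)
    expect_lt(abs(pes_energy(fix$pes, xt) - e0), 1e-9)
  }
})

test_that("relax_bfgs converges under the fmax rule and counts steps", {
  fix <- fixture_bonded()
  # start at the ground state: zero steps, converged
  rel0 <- relax_bfgs(fix$pes, fix$pes$x_star, fmax = 0.05)
  expect_true(rel0$converged)
  expect_identical(rel0$step_count, 0L)

  # re-relaxing a stored ground state changes the energy negligibly
  expect_lt(abs(rel0$energy - pes_energy(fix$pes, fix$pes$x_star)), 1e-8)

  # quadratic PES from any start: converges, energy does not increase
  pq <- build_pes(fix$top, "quadratic", seed = 2)
  set.seed(1)
  start <- pq$x_star + matrix(rnorm(15, 0, 0.3), 5, 3)
  rel <- relax_bfgs(pq, start, fmax = 0.05, max_steps = 500)
  expect_true(rel$converged)
  expect_lte(rel$energy, pes_energy(pq, start))
  expect_lte(rel$fmax_final, 0.05)

  # bonded system from a crude start within the step budget
  cs <- crude_start(fix$pes, seed = 5)
  relc <- relax_bfgs(fix$pes, cs, fmax = 0.05, max_steps = 500)
  expect_true(relc$converged)
  expect_lte(max(diffpes:::row_norms(pes_forces(fix$pes, relc$coords))), 0.05)

  # exceeding max_steps is reported, not raised
  rel_short <- relax_bfgs(fix$pes, cs, fmax = 1e-9, max_steps = 3)
  expect_false(rel_short$converged)
  expect_identical(rel_short$step_count, 3L)
})

test_that("relax_bfgs agrees with a reference optimizer on the minimum", {
  fix <- fixture_bonded()
  cs <- crude_start(fix$pes, seed = 9)
  rel <- relax_bfgs(fix$pes, cs, fmax = 1e-4, max_steps = 2000)
  ref <- stats::optim(
    diffpes:::flatten_coords(cs),
    fn = function(v) pes_energy(fix$pes, diffpes:::unflatten_coords(v)),
    gr = function(v) -diffpes:::flatten_coords(
      pes_forces(fix$pes, diffpes:::unflatten_coords(v))),
    method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(rel$energy, ref$value, tolerance = 1e-5)
})

test_that("generate_dataset is reproducible and stores verified ground states", {
  ds1 <- generate_dataset(10, c(4, 7), seed = 1)
  ds2 <- generate_dataset(10, c(4, 7), seed = 1)
  expect_identical(ds1, ds2)

  # every stored structure passes the fmax criterion when re-evaluated
  ok <- vapply(seq_along(ds1$systems), function(i) {
    pes <- ds1$pes_registry[[i]]
    max(diffpes:::row_norms(pes_forces(pes, ds1$systems[[i]]$coords))) <=
      ds1$fmax
  }, TRUE)
  expect_true(all(ok))

  # splits are disjoint and cover all systems
  expect_length(intersect(ds1$splits$train, ds1$splits$val), 0)
  expect_setequal(c(ds1$splits$train, ds1$splits$val),
                  seq_along(ds1$systems))

  # single diatomic at its exact bond length
  ab1 <- data.frame(species = "A", max_degree = 1L, radius = 0.37)
  dsd <- generate_dataset(1, c(2, 2), seed = 0, alphabet = ab1,
                          val_fraction = 0)
  d <- dist(dsd$systems[[1]]$coords)[1]
  expect_equal(as.numeric(d), 0.74, tolerance = 1e-3)
})

test_that("crude starts are systematically offset minima", {
  fix <- fixture_bonded()
  # zero perturbation returns the exact ground state
  cs0 <- crude_start(fix$pes, perturbation = list(length_sd = 0, angle_sd = 0,
                                                  k_sd = 0, shift_sd = 0),
                     seed = 1)
  expect_equal_mat(cs0, fix$pes$x_star, tol = 1e-6)

  # determinism
  expect_identical(crude_start(fix$pes, seed = 4), crude_start(fix$pes, seed = 4))

  # default perturbation: positive mean excess energy within the design band
  ds <- generate_dataset(25, c(5, 9), seed = 11)
  excess <- vapply(seq_along(ds$systems), function(i) {
    pes <- ds$pes_registry[[i]]
    pes_energy(pes, crude_start(pes, seed = i)) -
      pes_energy(pes, pes$x_star)
  }, 0)
  expect_true(all(excess > 0))
  expect_gt(mean(excess), 2)
  expect_lt(mean(excess), 20)

  # quadratic style: crude start is the shifted minimum
  pq <- fixture_quadratic_iso()
  csq <- crude_start(pq, seed = 2)
  expect_gt(pes_energy(pq, csq), pes_energy(pq, pq$x_star))
})

test_that("equipartition_reference gives d k_B T / 2 on quadratic surfaces", {
  pq <- fixture_quadratic_iso(kappa = 10, n_atoms = 2, seed = 0)
  # d = 6 free coordinates for a diatomic with a full-rank 6x6 Hessian
  expect_equal(equipartition_reference(pq, T = 1 / 3, k_b = 1), 1.0)
  expect_equal(equipartition_reference(pq, T = 0), 0)
  pq2 <- fixture_quadratic_iso(kappa = 3, n_atoms = 4, seed = 1)
  expect_equal(equipartition_reference(pq2, T = 1), 12 / 2)
  expect_error(equipartition_reference(fixture_bonded()$pes, T = 1),
               "quadratic")
})
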