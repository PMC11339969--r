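test_that("Metropolis-Hastings chains freeze at low temperature", {
  pq <- fixture_quadratic_iso(kappa = 10, n_atoms = 2)
  ch <- mh_chain(pq, T = 1e-8,
                 config = list(n_steps = 3000, burn_in = 500, seed = 1))
  expect_lt(mean(ch$energies), 1e-6)
  expect_true(all(is.finite(ch$energies)))
  expect_gte(ch$acceptance_rate, 0)
  expect_lte(ch$acceptance_rate, 1)
})

test_that("MH chains satisfy equipartition on quadratic surfaces", {
  # d free coordinates at temperature T: mean potential energy d k_B T / 2,
  # checked within 3 effective-sample-size-corrected standard errors
  for (case in list(list(nat = 2, kappa = 8, T = 0.3),
                    list(nat = 3, kappa = 20, T = 0.6))) {
    pq <- fixture_quadratic_iso(kappa = case$kappa, n_atoms = case$nat)
    ch <- mh_chain(pq, T = case$T,
                   config = list(n_steps = 16000, burn_in = 4000, seed = 7))
    want <- equipartition_reference(pq, case$T)
    ess <- diffpes:::effective_sample_size(ch$energies)
    se <- sd(ch$energies) / sqrt(ess)
    expect_lt(abs(mean(ch$energies) - want), 3 * se)
  }
})

test_that("MH equilibrium energies follow the Boltzmann (Gamma) law", {
  # for E = sum of d quadratic modes at temperature T, the potential energy is
  # Gamma(d/2, scale k_B T): compare bin occupancies (detailed-balance smoke)
  pq <- fixture_quadratic_iso(kappa = 5, n_atoms = 2)
  T <- 0.5
  ch <- mh_chain(pq, T, config = list(n_steps = 24000, burn_in = 5000, seed = 3))
  d <- 6
  cut <- qgamma(0.5, shape = d / 2, scale = T)
  frac <- mean(ch$energies > cut)
  ess <- diffpes:::effective_sample_size(ch$energies)
  se <- sqrt(0.25 / ess)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("MH mean energy is non-decreasing in temperature", {
  pq <- fixture_quadratic_iso(kappa = 10, n_atoms = 2)
  means <- vapply(c(0.1, 0.3, 0.6, 1.0), function(T) {
    mean(mh_chain(pq, T, config = list(n_steps = 8000, burn_in = 2000,
                                       seed = 5))$energies)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("fixed-step diffusion chains stay near zero in the no-noise limit", {
  fix <- fixture_bonded()
  lat <- encode_system(fix$system)
  sch <- make_schedule(500)
  den <- oracle_denoiser(lat, 0)
  ch <- diffusion_chain(den, fix$system, fix$pes, n = 1, sch,
                        config = list(n_steps = 300, burn_in = 50, seed = 2))
  expect_lt(max(abs(ch$energies)), 1e-4)
})

test_that("diffusion-chain stationary energy matches the AR closed form", {
  # with the Gaussian-data oracle on an isotropic quadratic PES the chain is
  # a linear-Gaussian map per CoM-free coordinate; its stationary variance is
  # derived here independently and compared with the simulated mean energy
  kappa <- 12
  tau2 <- 0.02
  nat <- 3
  pq <- fixture_quadratic_iso(kappa = kappa, n_atoms = nat, seed = 9)
  sys <- atomic_system(pq$topology$species, pq$x_star, id = "ar")
  sch <- make_schedule(500)
  den <- oracle_denoiser(encode_system(sys), tau2)
  for (n in c(10, 25)) {
    a_n <- diffpes:::sched_alpha(sch, n)
    a_p <- diffpes:::sched_alpha(sch, n - 1)
    s_n <- diffpes:::sched_sigma(sch, n)
    s_p <- diffpes:::sched_sigma(sch, n - 1)
    gam <- a_n / a_p
    s2c <- s_n^2 - gam^2 * s_p^2
    shrink <- a_n * tau2 / (a_n^2 * tau2 + s_n^2)
    c1 <- s2c * (1 - a_n * shrink) / (gam * s_n^2)
    a_coef <- 1 - c1 * gam
    sd_noise <- s_p * sqrt(s2c) / s_n / a_p
    var_st <- sd_noise^2 / (1 - a_coef^2)
    d_free <- 3 * (nat - 1)
    want <- 0.5 * kappa * d_free * var_st
    ch <- diffusion_chain(den, sys, pq, n, sch,
                          config = list(n_steps = 10000, burn_in = 2000,
                                        seed = 4))
    ## robust Monte-Carlo error from non-overlapping batch means
    bm <- colMeans(matrix(ch$energies, ncol = 20))
    se <- sd(bm) / sqrt(20)
    expect_lt(abs(mean(ch$energies) - want), 3 * se + 0.02 * want)
  }
})

test_that("diffusion-chain mean energy is non-decreasing in n (oracle)", {
  pq <- fixture_quadratic_iso(kappa = 10, n_atoms = 3, seed = 2)
  sys <- atomic_system(pq$topology$species, pq$x_star, id = "mono")
  sch <- make_schedule(500)
  den <- oracle_denoiser(encode_system(sys), 0.02)
  means <- vapply(c(5, 12, 25, 40), function(n) {
    mean(diffusion_chain(den, sys, pq, n, sch,
                         config = list(n_steps = 2500, burn_in = 500,
                                       seed = 6))$energies)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("repeated Gaussian perturbation diverges where the chain does not", {
  fix <- fixture_bonded()
  ctl <- gaussian_perturbation_chain(fix$pes, sigma = 0.01, n_steps = 3000,
                                     seed = 1)
  # the random walk's energy grows roughly linearly and without bound
  expect_gt(mean(ctl[2501:3000]), 10 * mean(ctl[1:500]))
  expect_gt(max(ctl), 50)

  # while the diffusion chain with the same per-step noise scale stays bounded
  sch <- make_schedule(500)
  den <- oracle_denoiser(encode_system(fix$system), 0.01)
  ch <- diffusion_chain(den, fix$system, fix$pes, n = 20, sch,
                        config = list(n_steps = 3000, burn_in = 500, seed = 1,
                                      ceiling = 1e3))
  expect_lt(max(ch$energies), max(ctl))
})

test_that("offset equalization recovers constructed shifts", {
  mk_chain <- function(vals, T = NA, n = NA, kind) {
    structure(list(energies = vals, acceptance_rate = 0.4,
                   proposal_sigma = 0.1, T = T, n = n, kind = kind,
                   samples = NULL, config = list()),
              class = "chain_result")
  }
  base <- rnorm(200, 1, 0.1)
  grp <- list(sys1 = list(
    mh = list(mk_chain(base, T = 0.1, kind = "mh"),
              mk_chain(base + 2, T = 0.5, kind = "mh")),
    diffusion = list(mk_chain(base + 0.7, n = 1L, kind = "diffusion"),
                     mk_chain(base + 3, n = 20L, kind = "diffusion"))))
  out <- equalize_offsets(grp)
  expect_equal(unname(out$constants["sys1"]), 0.7, tolerance = 1e-12)
  expect_equal(mean(out$chain_sets$sys1$diffusion[[1]]$energies),
               mean(base), tolerance = 1e-12)

  # identical chains need no constant
  grp0 <- list(s = list(mh = list(mk_chain(base, T = 0.1, kind = "mh")),
                        diffusion = list(mk_chain(base, n = 1L,
                                                  kind = "diffusion"))))
  expect_equal(unname(equalize_offsets(grp0)$constants["s"]), 0,
               tolerance = 1e-12)

  # constants above the bound warn but are still applied
  grp_big <- list(s = list(mh = list(mk_chain(base, T = 0.1, kind = "mh")),
                           diffusion = list(mk_chain(base + 5, n = 1L,
                                                     kind = "diffusion"))))
  expect_warning(out_big <- equalize_offsets(grp_big, bound = 2), "bound")
  expect_equal(unname(out_big$constants["s"]), 5, tolerance = 1e-12)
})

test_that("step-temperature calibration recovers known parameters", {
  # exact linear/quadratic inputs: mu = d/b to near machine precision
  T_grid <- seq(0.1, 1, length.out = 8)
  n_grid <- c(1, 3, 6, 10, 15, 20, 30, 40)
  b <- 2.5; a <- 0.3; d <- 0.004; cc <- 0.1
  mh <- data.frame(system = "s1", T = T_grid, mean_E = a + b * T_grid)
  df <- data.frame(system = "s1", n = n_grid, mean_E = cc + d * n_grid^2)
  cal <- calibrate_n_to_t(mh, df)
  expect_equal(cal$mu, d / b, tolerance = 1e-10)
  expect_equal(cal$r2_T, 1, tolerance = 1e-12)
  expect_equal(cal$r2_n2, 1, tolerance = 1e-12)

  # 1% relative noise: mu recovered to 5%
  set.seed(12)
  reps <- vapply(1:20, function(r) {
    mh_n <- mh; df_n <- df
    mh_n$mean_E <- mh_n$mean_E * (1 + rnorm(8, 0, 0.01))
    df_n$mean_E <- df_n$mean_E * (1 + rnorm(8, 0, 0.01))
    calibrate_n_to_t(mh_n, df_n)$mu
  }, 0)
  expect_lt(median(abs(reps - d / b) / (d / b)), 0.05)

  # two systems sharing mu with different intercepts: joint fit recovers it
  mh2 <- rbind(mh, transform(mh, system = "s2", mean_E = mean_E + 1.5))
  df2 <- rbind(df, transform(df, system = "s2", mean_E = mean_E + 0.9))
  cal2 <- calibrate_n_to_t(mh2, df2)
  expect_equal(cal2$mu, d / b, tolerance = 1e-10)

  # degenerate grids error
  expect_error(calibrate_n_to_t(transform(mh, mean_E = 1), df), "degenerate")
})
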