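#' Metropolis-Hastings chain on a toy PES
#'
#' Isotropic Gaussian proposals on all coordinates with the Boltzmann
#' acceptance rule `min(1, exp(-dE / (k_B T)))`, initialised at the PES ground
#' state. The proposal width is auto-tuned during burn-in toward a 30-50%
#' acceptance rate and frozen afterwards (retained samples therefore satisfy
#' detailed balance). Returned energies are relative to the ground state and
#' exclude burn-in.
#'
#' @param pes a `toy_pes`.
#' @param T temperature (toy units, `k_B = 1` by default).
#' @param config list: `n_steps` (default 24000), `burn_in` (default 5000),
#'   `proposal_sigma` (initial width, angstrom, default 0.02), `k_b`
#'   (default 1), `seed`, `tune` (default TRUE), `thin` (default 1),
#'   `keep_samples` (default FALSE).
#' @return a `chain_result`: list with `energies`, `acceptance_rate`,
#'   `proposal_sigma` (frozen value), `T`, `kind = "mh"`, optional `samples`,
#'   and the config echo.
#' @export
mh_chain <- function(pes, T, config = list()) {
  cfg <- utils::modifyList(
    list(n_steps = 24000, burn_in = 5000, proposal_sigma = 0.02, k_b = 1,
         seed = 0, tune = TRUE, thin = 1, keep_samples = FALSE), config)
  stopifnot(T > 0, cfg$burn_in < cfg$n_steps, cfg$proposal_sigma > 0)
  with_seed(derive_seed(cfg$seed, sprintf("mh-%g", T)), {
    x <- pes$x_star
    e0 <- pes_energy(pes, x)
    e <- e0
    sig <- cfg$proposal_sigma
    n_keep <- cfg$n_steps - cfg$burn_in
    energies <- numeric(n_keep)
    samples <- if (cfg$keep_samples) list() else NULL
    acc_kept <- 0
    acc_win <- 0
    for (i in seq_len(cfg$n_steps)) {
      prop <- x + matrix(stats::rnorm(length(x), 0, sig), nrow(x), 3)
      e_prop <- pes_energy(pes, prop)
      if (stats::runif(1) < exp(-(e_prop - e) / (cfg$k_b * T))) {
        x <- prop; e <- e_prop
        if (i <= cfg$burn_in) acc_win <- acc_win + 1 else acc_kept <- acc_kept + 1
      }
      if (cfg$tune && i <= cfg$burn_in && i %% 100 == 0) {
        rate <- acc_win / 100
        if (rate < 0.30) sig <- sig * 0.8
        if (rate > 0.50) sig <- sig * 1.25
        acc_win <- 0
      }
      if (i > cfg$burn_in) {
        k <- i - cfg$burn_in
        energies[k] <- e - e0
        if (cfg$keep_samples && k %% cfg$thin == 0) {
          samples[[length(samples) + 1]] <- x
        }
      }
    }
    structure(list(energies = energies, acceptance_rate = acc_kept / n_keep,
                   proposal_sigma = sig, T = T, n = NA_integer_, kind = "mh",
                   samples = samples, config = cfg),
              class = "chain_result")
  })
}

#' @export
print.chain_result <- function(x, ...) {
  lab <- if (x$kind == "mh") sprintf("MH, T=%g", x$T) else
    sprintf("diffusion, n=%d", x$n)
  cat(sprintf("<chain_result (%s): %d retained, mean E=%.4f, sd=%.4f>\n",
              lab, length(x$energies), mean(x$energies), stats::sd(x$energies)))
  invisible(x)
}

#' Fixed-step diffusion chain
#'
#' Repeatedly applies a single reverse-diffusion step at fixed `n` to a
#' structure: clean-encode at signal level `alpha_n`, one reverse step
#' `n -> n-1`, decode at `alpha_{n-1}` (the default re-entry convention; set
#' `latent_mode = TRUE` to instead stay at latent scale and re-noise to `n`
#' each iteration). Initialised at the ground state; energies are relative to
#' the ground state and exclude burn-in. The chain is asserted never to
#' diverge: a retained energy above `ceiling` aborts with a diagnostic.
#'
#' @param denoiser a denoiser object.
#' @param system an [atomic_system()] at the PES ground state.
#' @param pes the matching `toy_pes` (energy measurements).
#' @param n fixed diffusion step, `1 <= n <= N`.
#' @param schedule a `noise_schedule`.
#' @param config list: `n_steps` (default 20000), `burn_in` (default 1000),
#'   `seed`, `ceiling` (default 1e6), `latent_mode` (default FALSE),
#'   `alpha_floor`, `h_scale`, `keep_samples`, `thin`.
#' @return a `chain_result` with `kind = "diffusion"`.
#' @export
diffusion_chain <- function(denoiser, system, pes, n, schedule,
                            config = list()) {
  cfg <- utils::modifyList(
    list(n_steps = 20000, burn_in = 1000, seed = 0, ceiling = 1e6,
         latent_mode = FALSE, alpha_floor = 0.05, h_scale = 0.25,
         keep_samples = FALSE, thin = 1), config)
  stopifnot(n >= 1, n <= schedule$N, cfg$burn_in < cfg$n_steps)
  alphabet <- pes_alphabet(denoiser)
  lat <- encode_system(system, alphabet = alphabet, h_scale = cfg$h_scale)
  e0 <- pes_energy(pes, pes$x_star)
  with_seed(derive_seed(cfg$seed, sprintf("diff-%d", n)), {
    coords <- lat$x
    zlat <- NULL
    n_keep <- cfg$n_steps - cfg$burn_in
    energies <- numeric(n_keep)
    samples <- if (cfg$keep_samples) list() else NULL
    a_n <- sched_alpha(schedule, n)
    a_p <- sched_alpha(schedule, n - 1)
    meta <- list(alphabet = alphabet, h_scale = cfg$h_scale, id = system$id)
    for (i in seq_len(cfg$n_steps)) {
      if (cfg$latent_mode) {
        ## stay in latent scale; re-noise the running latent back up to n
        if (is.null(zlat)) zlat <- a_n * lat$x
        st <- diffusion_state(project_com(zlat), a_n * lat$h, n, meta)
        st <- reverse_step(st, denoiser, schedule)
        sig_up <- sqrt(max(0, sched_sigma(schedule, n)^2 -
                             (a_n / a_p)^2 * sched_sigma(schedule, n - 1)^2))
        zlat <- (a_n / a_p) * st$zx +
          sig_up * project_com(matrix(stats::rnorm(length(st$zx)),
                                      nrow(st$zx), 3))
        coords <- st$zx / max(a_p, cfg$alpha_floor)
      } else {
        st <- diffusion_state(a_n * project_com(coords), a_n * lat$h, n, meta)
        st <- reverse_step(st, denoiser, schedule)
        coords <- if (a_p < cfg$alpha_floor) st$zx else st$zx / a_p
      }
      e <- pes_energy(pes, coords) - e0
      if (!is.finite(e)) stop("non-finite energy in diffusion chain at iteration ", i)
      if (i > cfg$burn_in) {
        k <- i - cfg$burn_in
        energies[k] <- e
        if (e > cfg$ceiling) {
          stop("diffusion chain exceeded the energy ceiling at iteration ", i)
        }
        if (cfg$keep_samples && k %% cfg$thin == 0) {
          samples[[length(samples) + 1]] <- coords
        }
      }
    }
    structure(list(energies = energies, acceptance_rate = NA_real_,
                   proposal_sigma = NA_real_, T = NA_real_, n = as.integer(n),
                   kind = "diffusion", samples = samples, config = cfg),
              class = "chain_result")
  })
}

pes_alphabet <- function(denoiser) {
  denoiser$config$alphabet %||% default_alphabet()
}

#' Repeated isotropic Gaussian perturbation (divergence control)
#'
#' The contrast experiment for the diffusion chain: perturbing coordinates
#' with zero-mean Gaussian noise and no preferred direction makes the energy
#' grow without bound, unlike the diffusion chain which never diverges.
#'
#' @param pes a `toy_pes`.
#' @param sigma per-step perturbation SD, angstrom.
#' @param n_steps chain length.
#' @param seed integer seed.
#' @return numeric vector of energies relative to the ground state.
#' @export
gaussian_perturbation_chain <- function(pes, sigma = 0.01, n_steps = 2000,
                                        seed = 0) {
  with_seed(derive_seed(seed, "gauss-control"), {
    x <- pes$x_star
    e0 <- pes_energy(pes, x)
    out <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      x <- x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), 3)
      out[i] <- pes_energy(pes, x) - e0
    }
    out
  })
}

#' Equalize chain-family offsets at the low-noise anchors
#'
#' For each system, subtracts one constant from the diffusion-chain family so
#' that its minimum mean energy (at the lowest `n`) matches the MH family's
#' minimum mean energy (at the lowest `T`). Emits a warning when the constant
#' exceeds `bound` but still applies it.
#'
#' @param chain_sets named list (by system) of lists with elements `mh` and
#'   `diffusion`, each a list of `chain_result`s.
#' @param bound warn threshold on the constant (default 2 toy kcal/mol).
#' @return list with `chain_sets` (adjusted) and `constants` (named numeric).
#' @export
equalize_offsets <- function(chain_sets, bound = 2) {
  constants <- numeric(0)
  for (id in names(chain_sets)) {
    grp <- chain_sets[[id]]
    if (length(grp$mh) == 0 || length(grp$diffusion) == 0) {
      stop("group ", id, " must contain both chain families")
    }
    t_vals <- vapply(grp$mh, function(c) c$T, 0)
    n_vals <- vapply(grp$diffusion, function(c) c$n, 0L)
    anchor_mh <- mean(grp$mh[[which.min(t_vals)]]$energies)
    anchor_diff <- mean(grp$diffusion[[which.min(n_vals)]]$energies)
    const <- anchor_diff - anchor_mh
    if (abs(const) > bound) {
      warning(sprintf("offset constant %.3f for %s exceeds bound %.3f",
                      const, id, bound))
    }
    grp$diffusion <- lapply(grp$diffusion, function(c) {
      c$energies <- c$energies - const
      c
    })
    chain_sets[[id]] <- grp
    constants[id] <- const
  }
  list(chain_sets = chain_sets, constants = constants)
}

#' Summarise chain energies
#'
#' @param chains list of `chain_result`s.
#' @param system system id to attach.
#' @return data.frame with `system`, `kind`, `T`, `n`, `mean_E`, `sd_E`, `ess`.
#' @export
summarize_chains <- function(chains, system = "sys") {
  do.call(rbind, lapply(chains, function(c) {
    data.frame(system = system, kind = c$kind, T = c$T, n = c$n,
               mean_E = mean(c$energies), sd_E = stats::sd(c$energies),
               ess = effective_sample_size(c$energies))
  }))
}

#' Calibrate the diffusion-step to temperature mapping
#'
#' Least-squares fits `mean_E = a + b T` on the MH family and
#' `mean_E = c + d n^2` on the diffusion family (jointly across systems with
#' per-system intercepts when several are supplied), and returns the single
#' scaling factor `mu = d / b` such that `T_eff(n) = mu n^2` aligns the two
#' energy curves.
#'
#' @param mh_summary data.frame with columns `system`, `T`, `mean_E`.
#' @param diff_summary data.frame with columns `system`, `n`, `mean_E`.
#' @return a `calibration_result`: list with `slope_T`, `coeff_n2`,
#'   `intercepts` (per family/system), `mu`, `r2_T`, `r2_n2`.
#' @export
calibrate_n_to_t <- function(mh_summary, diff_summary) {
  stopifnot(nrow(mh_summary) >= 3, nrow(diff_summary) >= 3)
  if (stats::var(mh_summary$mean_E) == 0 || stats::var(diff_summary$mean_E) == 0) {
    stop("degenerate grid: constant mean energies")
  }
  multi_mh <- length(unique(mh_summary$system)) > 1
  multi_df <- length(unique(diff_summary$system)) > 1
  fit_mh <- if (multi_mh) {
    stats::lm(mean_E ~ 0 + factor(system) + T, data = mh_summary)
  } else stats::lm(mean_E ~ T, data = mh_summary)
  diff_summary$n2 <- diff_summary$n^2
  fit_df <- if (multi_df) {
    stats::lm(mean_E ~ 0 + factor(system) + n2, data = diff_summary)
  } else stats::lm(mean_E ~ n2, data = diff_summary)
  b <- unname(stats::coef(fit_mh)["T"])
  d <- unname(stats::coef(fit_df)["n2"])
  r2 <- function(fit, y) 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    slope_T = b, coeff_n2 = d, mu = d / b,
    intercepts = list(mh = stats::coef(fit_mh)[names(stats::coef(fit_mh)) != "T"],
                      diffusion = stats::coef(fit_df)[names(stats::coef(fit_df)) != "n2"]),
    r2_T = r2(fit_mh, mh_summary$mean_E),
    r2_n2 = r2(fit_df, diff_summary$mean_E)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration: slope_T=%.5g, coeff_n2=%.5g, mu=%.5g, R2(T)=%.4f, R2(n2)=%.4f>\n",
    x$slope_T, x$coeff_n2, x$mu, x$r2_T, x$r2_n2))
  invisible(x)
}

#' Default temperature and step grids for the chain study
#'
#' 18 temperatures and 14 steps spanning 1..40 (toy units, `k_B = 1`). The
#' lowest temperature sits essentially at zero: it is the anchor at which
#' [equalize_offsets()] aligns the two chain families, so its mean energy
#' must be negligible against the rest of the grid.
#'
#' @param t_max top of the temperature grid (toy units).
#' @return list with `T_grid` (length 18) and `n_grid` (length 14).
#' @export
default_chain_grids <- function(t_max = 0.8) {
  list(T_grid = c(0.002, seq(t_max / 16, t_max, length.out = 17)),
       n_grid = unique(round(c(1, 2, 3, 4, 6, 8, 10, 13, 16, 20, 24, 29, 34, 40))))
}
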