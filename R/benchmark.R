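#' Partial-diffusion structure relaxation
#'
#' Runs the last `n` reverse-diffusion steps starting from a user-supplied
#' structure: the input is clean-encoded and scaled by `alpha_n` (no forward
#' noise is added — the input is an already-built geometry, not a noised
#' one; set `noised = TRUE` for the sensitivity variant), then reverse steps
#' `n -> 0` are applied and the full path is recorded. With
#' `freeze_species = TRUE` the species channels are clamped to the clean
#' one-hot at every step; by default they evolve freely and a post-hoc check
#' flags (without raising) any species change.
#'
#' @param denoiser a denoiser object.
#' @param system an [atomic_system()] to relax.
#' @param n number of diffusion steps to run (`0` returns the input unchanged).
#' @param schedule a `noise_schedule`.
#' @param seed integer seed.
#' @param freeze_species clamp species channels (default FALSE).
#' @param noised add forward noise at step n instead of plain scaling.
#' @param h_scale one-hot scale.
#' @param alpha_floor decoding guard.
#' @return list with `trajectory` (a `diff_trajectory`), `final`
#'   ([atomic_system()]), `species_changed` flag.
#' @export
partial_relax <- function(denoiser, system, n, schedule, seed = 0,
                          freeze_species = FALSE, noised = FALSE,
                          h_scale = 0.25, alpha_floor = 0.05) {
  stopifnot(n >= 0, n <= schedule$N)
  alphabet <- pes_alphabet(denoiser)
  lat <- encode_system(system, alphabet = alphabet, h_scale = h_scale)
  if (n == 0) {
    st <- forward_noise(lat, 0, schedule)
    traj <- as_trajectory(list(st), schedule, alpha_floor)
    return(list(trajectory = traj, final = decode_state(st, schedule),
                species_changed = FALSE))
  }
  with_seed(derive_seed(seed, paste0("prelax-", system$id)), {
    a_n <- sched_alpha(schedule, n)
    meta <- list(alphabet = alphabet, h_scale = h_scale, id = system$id)
    state <- if (noised) {
      forward_noise(lat, n, schedule)
    } else {
      diffusion_state(a_n * lat$x, a_n * lat$h, n, meta)
    }
    states <- vector("list", n + 1)
    states[[1]] <- state
    for (step in n:1) {
      state <- reverse_step(state, denoiser, schedule)
      if (freeze_species) {
        state$zh <- sched_alpha(schedule, state$n) * lat$h
      }
      states[[n - step + 2]] <- state
    }
    traj <- as_trajectory(states, schedule, alpha_floor)
    final <- traj$decoded[[length(traj$decoded)]]
    changed <- !identical(final$species, system$species)
    list(trajectory = traj, final = final, species_changed = changed)
  })
}

#' Relative energy along a relaxation path
#'
#' Energy of each decoded frame minus the tracked ground-state energy.
#'
#' @param pes a `toy_pes`.
#' @param traj a `diff_trajectory`.
#' @return numeric vector, one value per frame.
#' @export
relaxation_curve <- function(pes, traj) {
  e0 <- pes_energy(pes, pes$x_star)
  vapply(traj$decoded, function(s) pes_energy(pes, s$coords) - e0, 0)
}

#' Relaxation-initialization speedup benchmark
#'
#' For every system: generate its crude start, relax it directly with BFGS
#' (`steps_crude`), and for each `n` refine the crude start with
#' [partial_relax()] and relax the refined structure with identical optimizer
#' settings (`steps_diffused`). Records both iteration counts, the starting
#' energies of both arms relative to the ground state, and the energy delta
#' between the two final relaxed structures (relaxed-from-crude minus
#' relaxed-from-diffused; nonzero means the two starts fell into different
#' PES basins). Non-converged records are flagged (and excluded from
#' summaries by default).
#'
#' Both arms use a conservative per-step trust radius (`max_disp`, default
#' 0.01 angstrom): workflows whose force evaluations are expensive take
#' deliberately cautious steps, which places the iteration count in the
#' path-length-limited regime where a closer starting point genuinely saves
#' optimizer work. (With an aggressive trust radius on small analytic
#' systems, quasi-Newton counts are curvature-dominated and nearly
#' insensitive to the start.)
#'
#' @param denoiser a denoiser object.
#' @param dataset a `ground_state_dataset`.
#' @param schedule a `noise_schedule`.
#' @param n_values diffusion step counts to benchmark (default `c(20, 50)`).
#' @param fmax optimizer convergence criterion.
#' @param seed integer seed.
#' @param max_steps optimizer budget per arm.
#' @param max_disp per-step displacement cap for both arms, angstrom.
#' @param perturbation crude-start jitter configuration ([crude_start()]).
#' @param indices subset of systems to benchmark (default: all).
#' @return data.frame of benchmark records.
#' @export
benchmark_speedup <- function(denoiser, dataset, schedule,
                              n_values = c(20, 50), fmax = 0.05, seed = 0,
                              max_steps = 1000, max_disp = 0.01,
                              perturbation = list(), indices = NULL) {
  indices <- indices %||% seq_along(dataset$systems)
  rows <- list()
  for (i in indices) {
    sys <- dataset$systems[[i]]
    pes <- dataset$pes_registry[[sys$id]]
    e0 <- pes_energy(pes, pes$x_star)
    crude <- crude_start(pes, perturbation = perturbation,
                         seed = derive_seed(seed, paste0("crude-", sys$id)))
    arm_crude <- relax_bfgs(pes, crude, fmax = fmax, max_steps = max_steps,
                            max_disp = max_disp)
    crude_sys <- atomic_system(sys$species, crude, id = sys$id)
    for (n in n_values) {
      pr <- partial_relax(denoiser, crude_sys, n, schedule,
                          seed = derive_seed(seed, sprintf("pr-%s-%d", sys$id, n)))
      refined <- project_com(pr$final$coords)
      arm_diff <- relax_bfgs(pes, refined, fmax = fmax, max_steps = max_steps,
                             max_disp = max_disp)
      rows[[length(rows) + 1]] <- data.frame(
        system = sys$id, n_used = n, n_atoms = length(sys$species),
        steps_crude = arm_crude$step_count,
        steps_diffused = arm_diff$step_count,
        E_rel_crude = pes_energy(pes, crude) - e0,
        E_rel_diffused = pes_energy(pes, refined) - e0,
        delta_E = arm_crude$energy - arm_diff$energy,
        converged = arm_crude$converged && arm_diff$converged,
        species_changed = pr$species_changed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise speedup benchmark records
#'
#' Percent step reduction per record is
#' `100 (steps_crude - steps_diffused) / steps_crude`. Reports median and
#' quartiles, the fraction of records whose `|delta_E|` exceeds the exclusion
#' threshold, and the same statistics recomputed on the subset passing the
#' threshold (the "excluded variant"). Non-converged records are dropped
#' first.
#'
#' @param records data.frame from [benchmark_speedup()].
#' @param exclusion_threshold energy-delta cut, toy kcal/mol (default 0.2).
#' @return a `speedup_summary` list.
#' @export
summarize_speedup <- function(records, exclusion_threshold = 0.2) {
  stopifnot(nrow(records) >= 1)
  rec <- records[records$converged, , drop = FALSE]
  if (nrow(rec) == 0) stop("no unflagged (converged) records to summarise")
  pct <- 100 * (rec$steps_crude - rec$steps_diffused) / rec$steps_crude
  qs <- stats::quantile(pct, c(0.25, 0.5, 0.75), names = FALSE)
  keep <- abs(rec$delta_E) <= exclusion_threshold
  qs_ex <- if (any(keep)) {
    stats::quantile(pct[keep], c(0.25, 0.5, 0.75), names = FALSE)
  } else rep(NA_real_, 3)
  structure(list(
    n_records = nrow(rec),
    n_flagged = sum(!records$converged),
    pct_reduction = stats::setNames(qs, c("q25", "median", "q75")),
    frac_above_threshold = mean(!keep),
    exclusion_threshold = exclusion_threshold,
    n_excluded_variant = sum(keep),
    pct_reduction_excluded = stats::setNames(qs_ex, c("q25", "median", "q75"))),
    class = "speedup_summary")
}

#' @export
print.speedup_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<speedup_summary: %d records (%d flagged), median reduction ",
           "%.1f%% [%.1f, %.1f], %.1f%% above |dE|>%.2g; excluded-variant ",
           "median %.1f%%>\n"),
    x$n_records, x$n_flagged, x$pct_reduction["median"],
    x$pct_reduction["q25"], x$pct_reduction["q75"],
    100 * x$frac_above_threshold, x$exclusion_threshold,
    x$pct_reduction_excluded["median"]))
  invisible(x)
}
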