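#' Sum of the next k diffusion displacements
#'
#' `delta_k` at frame `i` is the sum of the next `k` decoded per-step
#' displacements, i.e. `decoded[i + k] - decoded[i]` by telescoping.
#'
#' @param traj a `diff_trajectory`.
#' @param frame frame index (1-based position in the decoded sequence).
#' @param k lookahead count (>= 1).
#' @return `n x 3` matrix.
#' @export
delta_k <- function(traj, frame, k = 1) {
  stopifnot(k >= 1)
  if (frame + k > length(traj$decoded)) {
    stop("k exceeds the remaining steps of the trajectory")
  }
  Reduce(`+`, traj$deltas[frame:(frame + k - 1)])
}

#' Direction from a geometry straight to the ground state
#'
#' Computes `gs_coords - coords` after aligning centres of mass (no rotational
#' superposition by default; see `kabsch`).
#'
#' @param coords current `n x 3` coordinates.
#' @param gs_coords ground-state `n x 3` coordinates.
#' @param kabsch also remove the optimal rigid rotation before subtracting.
#' @return `n x 3` matrix of per-atom direction vectors.
#' @export
gs_direction <- function(coords, gs_coords, kabsch = FALSE) {
  stopifnot(all(dim(coords) == dim(gs_coords)))
  a <- project_com(as.matrix(coords))
  b <- project_com(as.matrix(gs_coords))
  if (kabsch) {
    s <- svd(crossprod(b, a))        # rotate gs frame onto the current frame
    d <- sign(det(s$u %*% t(s$v)))
    r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    b <- b %*% r
  }
  b - a
}

#' Cosine similarity between two per-atom vector fields
#'
#' Mode `"per-atom-mean"` (default) computes the 3D cosine per atom and
#' averages over atoms, excluding atoms where either vector norm is below
#' `1e-12`; mode `"flat"` computes one cosine between the flattened 3n
#' vectors.
#'
#' @param u,v `n x 3` matrices.
#' @param mode `"per-atom-mean"` or `"flat"`.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_field <- function(u, v, mode = c("per-atom-mean", "flat")) {
  mode <- match.arg(mode)
  u <- as.matrix(u); v <- as.matrix(v)
  stopifnot(all(dim(u) == dim(v)))
  if (mode == "flat") {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12) stop("degenerate (near-zero) vector field")
    return(sum(u * v) / (nu * nv))
  }
  nu <- row_norms(u); nv <- row_norms(v)
  keep <- nu >= 1e-12 & nv >= 1e-12
  if (!any(keep)) stop("all atoms excluded: near-zero vectors in both fields")
  mean(rowSums(u[keep, , drop = FALSE] * v[keep, , drop = FALSE]) /
         (nu[keep] * nv[keep]))
}

#' Closed-form force/ground-state alignment on a quadratic PES
#'
#' On `E = 1/2 d' H d` the forces are `f = -H d` and the ground-state
#' direction is `gs = -d`, so the flat-mode cosine is
#' `cos(f, gs) = d' H d / (|H d| |d|)` — equal to 1 for isotropic `H` and
#' strictly below 1 for anisotropic `H` and generic `d`. This is the
#' curvature statistic the alignment analysis probes.
#'
#' @param hessian PSD matrix `H`.
#' @param displacement vector `d` (non-zero).
#' @return scalar cosine.
#' @export
analytic_quadratic_alignment <- function(hessian, displacement) {
  d <- as.numeric(displacement)
  if (sqrt(sum(d^2)) < 1e-14) stop("zero displacement")
  hd <- as.numeric(as.matrix(hessian) %*% d)
  sum(d * hd) / (sqrt(sum(hd^2)) * sqrt(sum(d^2)))
}

#' Cosine-alignment analysis of diffusion steps vs forces vs ground state
#'
#' For each system, runs a partial-diffusion relaxation from its crude start
#' and records, at every step with at least `k` remaining, the cosine between
#' the summed model displacement `delta_k` and (a) the analytic forces `f`
#' at the current geometry, (b) the straight direction `gs` to the ground
#' state — plus the reference `cos(f, gs)`.
#'
#' @param denoiser a denoiser object.
#' @param systems list of [atomic_system()] starting structures (typically
#'   crude starts).
#' @param pes_map named list id -> `toy_pes` (ground states must be tracked).
#' @param schedule a `noise_schedule`.
#' @param ks lookahead counts (default `c(1, 10, 30)`).
#' @param n_start diffusion step to start the relaxation at.
#' @param seed integer seed.
#' @param mode cosine mode, see [cosine_field()].
#' @return data.frame with columns `system`, `n`, `k`, `cos_df`, `cos_dgs`,
#'   `cos_fgs`.
#' @export
alignment_analysis <- function(denoiser, systems, pes_map, schedule,
                               ks = c(1, 10, 30), n_start = 50, seed = 0,
                               mode = "per-atom-mean") {
  rows <- list()
  for (s in systems) {
    pes <- pes_map[[s$id]]
    if (is.null(pes)) stop("no PES registered for system ", s$id)
    pr <- partial_relax(denoiser, s, n_start, schedule,
                        seed = derive_seed(seed, s$id))
    traj <- pr$trajectory
    nf <- length(traj$decoded)
    for (i in seq_len(nf - 1)) {
      coords <- traj$decoded[[i]]$coords
      f <- pes_forces(pes, coords)
      gs <- gs_direction(coords, pes$x_star)
      cfg <- tryCatch(cosine_field(f, gs, mode), error = function(e) NA_real_)
      for (k in ks[ks <= nf - i]) {
        dk <- delta_k(traj, i, k)
        rows[[length(rows) + 1]] <- data.frame(
          system = s$id, n = traj$steps[i], k = k,
          cos_df = tryCatch(cosine_field(dk, f, mode),
                            error = function(e) NA_real_),
          cos_dgs = tryCatch(cosine_field(dk, gs, mode),
                             error = function(e) NA_real_),
          cos_fgs = cfg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise an alignment table across systems
#'
#' @param records output of [alignment_analysis()].
#' @return data.frame with per-(n, k) means and SDs of the three cosines.
#' @export
summarize_alignment <- function(records) {
  agg <- stats::aggregate(records[c("cos_df", "cos_dgs", "cos_fgs")],
                          by = records[c("n", "k")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  sdv <- stats::aggregate(records[c("cos_df", "cos_dgs", "cos_fgs")],
                          by = records[c("n", "k")],
                          FUN = function(v) stats::sd(v, na.rm = TRUE))
  names(sdv)[3:5] <- paste0(names(sdv)[3:5], "_sd")
  merge(agg, sdv, by = c("n", "k"))
}
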