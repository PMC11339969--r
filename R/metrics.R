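#' Per-step step sizes of a trajectory
#'
#' L2 norm over all atoms of the per-step decoded coordinate displacement,
#' one value per transition (length `frames - 1`).
#'
#' @param traj a `diff_trajectory`.
#' @return numeric vector.
#' @export
step_sizes <- function(traj) {
  if (length(traj$decoded) < 2) stop("trajectory needs at least 2 frames")
  vapply(traj$deltas, function(d) sqrt(sum(d^2)), 0)
}

#' Per-step mean absolute bond-length error
#'
#' Mean over bonded pairs of the absolute deviation between the current and
#' final interatomic distance; pairs are taken from the final structure
#' (perceived or known topology).
#'
#' @param traj a `diff_trajectory`.
#' @param bonds `m x 2` pair list; default: bonds perceived on the final frame.
#' @param radii per-species radii for perception (used when `bonds` is NULL).
#' @param tol perception tolerance, angstrom.
#' @return numeric vector, one value per frame.
#' @export
bond_length_error <- function(traj, bonds = NULL,
                              radii = NULL, tol = 0.45) {
  final <- traj$decoded[[length(traj$decoded)]]
  if (is.null(bonds)) {
    bonds <- perceive_bonds(final, radii = radii, tol = tol)
  }
  bonds <- as.matrix(bonds)
  if (nrow(bonds) == 0) stop("empty bond list")
  dist_of <- function(coords) {
    sqrt(rowSums((coords[bonds[, 1], , drop = FALSE] -
                  coords[bonds[, 2], , drop = FALSE])^2))
  }
  d_final <- dist_of(final$coords)
  vapply(traj$decoded, function(s) mean(abs(dist_of(s$coords) - d_final)), 0)
}

#' Fraction of atoms/molecules with finalized species per step
#'
#' An atom is *finalized* at a frame iff its decoded species equals the final
#' species at that frame and at every later frame (the stability definition —
#' this makes the series monotone non-decreasing as n decreases). The
#' molecule-level series requires all atoms finalized. A point-in-time variant
#' (`stability = FALSE`) is also available.
#'
#' @param traj a `diff_trajectory`.
#' @param stability use the stable-until-the-end definition (default TRUE).
#' @return list with `atom` and `mol` numeric vectors (fractions in `[0,1]`,
#'   one per frame).
#' @export
element_finalized <- function(traj, stability = TRUE) {
  sp <- do.call(rbind, lapply(traj$decoded, function(s) s$species))
  nf <- nrow(sp)
  final <- sp[nf, ]
  eq <- sweep_equal(sp, final)
  fin <- if (stability) {
    ## stable from this frame to the end: reverse cumulative AND
    apply(eq[nf:1, , drop = FALSE], 2, cumprod)[nf:1, , drop = FALSE] > 0
  } else eq
  list(atom = rowMeans(fin), mol = apply(fin, 1, all) * 1)
}

sweep_equal <- function(mat, ref) {
  t(apply(mat, 1, function(r) r == ref))
}

#' Perceive bonds from interatomic distances
#'
#' Pair `(i, j)` is bonded iff `d_ij <= r_i + r_j + tol` with per-species
#' radii. Symmetric, no self pairs. Radii default to the package alphabet's
#' covalent-like radii; the default tolerance is calibrated so that perceived
#' bonds match the generating topology on at least 95% of ground-state
#' systems.
#'
#' @param system an [atomic_system()].
#' @param radii named numeric vector (species -> radius) or NULL for the
#'   default alphabet radii.
#' @param tol tolerance, angstrom.
#' @return `m x 2` integer matrix, `i < j`.
#' @export
perceive_bonds <- function(system, radii = NULL, tol = 0.45) {
  if (is.null(radii)) {
    ab <- default_alphabet()
    radii <- stats::setNames(ab$radius, ab$species)
  }
  r <- radii[system$species]
  if (anyNA(r)) stop("radii undefined for species: ",
                     paste(unique(system$species[is.na(r)]), collapse = ", "))
  n <- length(r)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  d <- as.matrix(stats::dist(system$coords))
  cut <- outer(r, r, `+`) + tol
  hit <- which(upper.tri(d) & d <= cut, arr.ind = TRUE)
  unname(hit[order(hit[, 1], hit[, 2]), , drop = FALSE])
}

#' Bond-order finalization and validity metrics per step
#'
#' Per frame, bonds are perceived and each atom's degree (bond count) is
#' compared with (a) its degree in the final frame — *finalized*, using the
#' same stability definition as [element_finalized()] — and (b) the valence
#' table — *valid*. "Bond order" means degree count throughout.
#'
#' @param traj a `diff_trajectory`.
#' @param radii perception radii (see [perceive_bonds()]).
#' @param valence_table named list species -> vector of allowed degrees, or
#'   NULL for exactly the alphabet's maximum degrees `1..max`.
#' @param tol perception tolerance.
#' @param stability use the stable-until-the-end definition.
#' @return list with numeric vectors `atom_bo_final`, `mol_bo_final`,
#'   `atom_valid_bo` (one per frame).
#' @export
bond_order_metrics <- function(traj, radii = NULL, valence_table = NULL,
                               tol = 0.45, stability = TRUE) {
  if (is.null(valence_table)) {
    ab <- default_alphabet()
    valence_table <- stats::setNames(
      lapply(ab$max_degree, function(m) seq_len(m)), ab$species)
  }
  degs <- lapply(traj$decoded, function(s) {
    b <- perceive_bonds(s, radii = radii, tol = tol)
    tabulate(c(b[, 1], b[, 2]), length(s$species))
  })
  dmat <- do.call(rbind, degs)
  nf <- nrow(dmat)
  eq <- t(apply(dmat, 1, function(r) r == dmat[nf, ]))
  fin <- if (stability) {
    apply(eq[nf:1, , drop = FALSE], 2, cumprod)[nf:1, , drop = FALSE] > 0
  } else eq
  valid <- do.call(rbind, lapply(seq_len(nf), function(i) {
    sp <- traj$decoded[[i]]$species
    mapply(function(s, d) d %in% (valence_table[[s]] %||% integer(0)),
           sp, dmat[i, ])
  }))
  list(atom_bo_final = rowMeans(fin),
       mol_bo_final = apply(fin, 1, all) * 1,
       atom_valid_bo = rowMeans(valid))
}

#' Locate the exploration-to-relaxation regime boundary
#'
#' Returns the largest diffusion step at which all atomic species are
#' finalized (stability definition): above it the sampler is still choosing
#' atom identities ("exploration"), below it only coordinates move
#' ("relaxation"). Under the stability definition the final frame is always
#' finalized; if that is the *only* finalized frame (species never settle
#' before the very end), 0 is returned with a `warning_flag` attribute.
#'
#' @param traj a `diff_trajectory`.
#' @return integer step; attribute `warning_flag` TRUE when the species only
#'   settle at the final frame of a multi-frame trajectory.
#' @export
regime_split <- function(traj) {
  ef <- element_finalized(traj, stability = TRUE)
  idx <- which(ef$mol >= 1)
  if (min(idx) == length(ef$mol) && length(ef$mol) > 1) {
    out <- 0L
    attr(out, "warning_flag") <- TRUE
    warning("species never finalized before the last step; returning 0")
    return(out)
  }
  out <- as.integer(traj$steps[min(idx)])
  attr(out, "warning_flag") <- FALSE
  out
}

#' Aggregate inference metrics over a set of trajectories
#'
#' Computes all per-step series (step size, bond-length error, element and
#' bond-order finalization, valence validity) for each trajectory and
#' aggregates mean and SD across trajectories on the shared step axis.
#'
#' @param trajs list of `diff_trajectory`s sharing a step axis.
#' @param radii,tol perception settings.
#' @return data.frame with columns `step`, `metric`, `mean`, `sd`.
#' @export
metric_series <- function(trajs, radii = NULL, tol = 0.45) {
  stopifnot(length(trajs) >= 1)
  steps <- trajs[[1]]$steps
  per_traj <- lapply(trajs, function(tr) {
    ef <- element_finalized(tr)
    bo <- bond_order_metrics(tr, radii = radii, tol = tol)
    ble <- tryCatch(bond_length_error(tr, radii = radii, tol = tol),
                    error = function(e) rep(NA_real_, length(tr$decoded)))
    list(step_size = c(NA, step_sizes(tr)),
         bond_length_error = ble,
         atom_elem_final = ef$atom, mol_elem_final = ef$mol,
         atom_bo_final = bo$atom_bo_final, mol_bo_final = bo$mol_bo_final,
         atom_valid_bo = bo$atom_valid_bo)
  })
  metrics <- names(per_traj[[1]])
  out <- do.call(rbind, lapply(metrics, function(m) {
    vals <- do.call(rbind, lapply(per_traj, `[[`, m))
    data.frame(step = steps, metric = m,
               mean = colMeans(vals, na.rm = TRUE),
               sd = apply(vals, 2, stats::sd, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
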