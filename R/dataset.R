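#' Generate a synthetic ground-state dataset
#'
#' Builds `n_systems` toy molecules: each gets a random valence-respecting
#' topology, an analytic PES sharing one global toy force field, and a
#' relaxed, tracked ground-state geometry. The result stands in for a corpus
#' of quantum-chemistry-relaxed small molecules as diffusion training data.
#' Train/validation splits are stratified by system size. Fully reproducible
#' given `seed`.
#'
#' @param n_systems number of systems (>= 1).
#' @param atom_range integer `(min, max)` atoms per system.
#' @param seed integer seed.
#' @param style PES style for all systems, `"bonded"` or `"quadratic"`.
#' @param alphabet species table ([default_alphabet()]).
#' @param fmax ground-state force tolerance.
#' @param val_fraction fraction of systems held out for validation.
#' @param params optional PES parameter overrides (see [build_pes()]).
#' @return a `ground_state_dataset`: list with `systems` (list of
#'   [atomic_system()] at their ground states), `pes_registry` (named list of
#'   `toy_pes`), `splits` (`$train`, `$val` index vectors), `seed`.
#' @export
generate_dataset <- function(n_systems, atom_range = c(5, 12), seed = 0,
                             style = "bonded", alphabet = default_alphabet(),
                             fmax = 0.05, val_fraction = 0.2, params = list()) {
  stopifnot(n_systems >= 1, length(atom_range) == 2,
            atom_range[1] >= 2, atom_range[2] >= atom_range[1])
  systems <- vector("list", n_systems)
  registry <- vector("list", n_systems)
  sizes <- integer(n_systems)
  for (i in seq_len(n_systems)) {
    si <- derive_seed(seed, paste0("system", i))
    n_at <- with_seed(si, {
      sizes <- seq(atom_range[1], atom_range[2])
      sizes[sample.int(length(sizes), 1)]
    })
    top <- sample_topology(n_at, alphabet, seed = derive_seed(si, "topology"))
    pes <- build_pes(top, style = style, params = params,
                     seed = derive_seed(si, "pes"), alphabet = alphabet,
                     fmax = fmax)
    id <- sprintf("sys%04d", i)
    systems[[i]] <- atomic_system(top$species, pes$x_star, id = id)
    registry[[i]] <- pes
    sizes[i] <- n_at
  }
  names(registry) <- vapply(systems, function(s) s$id, "")
  splits <- stratified_split(sizes, val_fraction, derive_seed(seed, "split"))
  structure(list(systems = systems, pes_registry = registry, splits = splits,
                 seed = seed, fmax = fmax, style = style),
            class = "ground_state_dataset")
}

## Deterministic split stratified by size: within each size class, a fixed
## fraction goes to validation.
stratified_split <- function(sizes, val_fraction, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (s in sort(unique(sizes))) {
      idx <- which(sizes == s)
      k <- floor(length(idx) * val_fraction)
      if (k > 0) val <- c(val, sample(idx, k))
    }
    ## always keep at least one system in each split when possible
    if (length(val) == 0 && length(sizes) > 1) val <- length(sizes)
    train <- setdiff(seq_along(sizes), val)
    list(train = sort(train), val = sort(val))
  })
}

#' @export
print.ground_state_dataset <- function(x, ...) {
  cat(sprintf(
    "<ground_state_dataset: %d systems (%s PES), %d train / %d val, seed %d>\n",
    length(x$systems), x$style, length(x$splits$train), length(x$splits$val),
    x$seed))
  invisible(x)
}

#' Generate a crude (classical-force-field-like) starting geometry
#'
#' Emulates a structure relaxed with a cheap force field: the true PES is
#' cloned with jittered parameters (equilibrium bond lengths and angles,
#' force constants; for quadratic surfaces, a shifted minimum) and the clone
#' is relaxed starting from the true ground state. The returned geometry is
#' therefore a *systematically offset* minimum — several toy kcal/mol above
#' the true ground state on average — rather than isotropic noise.
#'
#' @param pes a `toy_pes`.
#' @param perturbation list of jitter scales: `length_sd` (multiplicative SD on
#'   equilibrium bond lengths), `angle_sd` (on equilibrium angles), `k_sd` (on
#'   force constants), `shift_sd` (additive SD in angstrom on the quadratic
#'   minimum). Scale 0 returns the true ground state. The defaults put the
#'   crude structures a few toy kcal/mol above the ground state, with
#'   per-atom displacements of one to a few tenths of an angstrom.
#' @param seed integer seed.
#' @return `n x 3` coordinate matrix (CoM-centred).
#' @export
crude_start <- function(pes,
                        perturbation = list(length_sd = 0.08, angle_sd = 0.06,
                                            k_sd = 0.1, shift_sd = 0.15),
                        seed = 0) {
  p <- utils::modifyList(list(length_sd = 0.08, angle_sd = 0.06, k_sd = 0.1,
                              shift_sd = 0.15), perturbation)
  with_seed(derive_seed(seed, "crude"), {
    if (pes$style == "quadratic") {
      shift <- matrix(stats::rnorm(length(pes$x_star), 0, p$shift_sd),
                      nrow(pes$x_star), 3)
      return(project_com(pes$x_star + shift))
    }
    pert <- pes
    ff <- pes$ff
    ff$r0 <- ff$r0 * stats::rnorm(length(ff$r0), 1, p$length_sd)
    ff$theta0 <- ff$theta0 * stats::rnorm(length(ff$theta0), 1, p$angle_sd)
    ff$k_bond <- ff$k_bond * abs(stats::rnorm(length(ff$k_bond), 1, p$k_sd))
    ff$k_angle <- ff$k_angle * abs(stats::rnorm(length(ff$k_angle), 1, p$k_sd))
    pert$ff <- ff
    rel <- relax_bfgs(pert, pes$x_star, fmax = pes$fmax, max_steps = 1000)
    if (!rel$converged) stop("perturbed-PES relaxation failed to converge")
    project_com(rel$coords)
  })
}

#' Serialize a ground-state dataset to a single JSON archive
#'
#' Plain (uncompressed) JSON is the one supported dialect: it keeps archives
#' text-only and byte-identical across reruns with the same seed. PES
#' parameters, coordinates, species, splits and the seed are stored;
#' [load_dataset()] rebuilds the `toy_pes` objects.
#'
#' @param dataset a `ground_state_dataset`.
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  enc <- list(
    format = "diffpes-dataset", version = 1L,
    seed = dataset$seed, fmax = dataset$fmax, style = dataset$style,
    splits = dataset$splits,
    systems = lapply(seq_along(dataset$systems), function(i) {
      s <- dataset$systems[[i]]
      pes <- dataset$pes_registry[[i]]
      rec <- list(id = s$id, species = s$species,
                  coords = signif(s$coords, 15),
                  bonds = pes$topology$bonds,
                  angles = pes$topology$angles,
                  ff = pes$ff[c("r0", "k_bond", "theta0", "k_angle",
                                "a_rep", "r_rep", "radius")])
      if (pes$style == "quadratic") {
        rec$hessian <- signif(pes$hessian, 15)
        rec$x_star <- signif(pes$x_star, 15)
      }
      rec
    })
  )
  json <- jsonlite::toJSON(enc, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Load a ground-state dataset archive written by [save_dataset()]
#'
#' @param path archive path.
#' @return a `ground_state_dataset`.
#' @export
load_dataset <- function(path) {
  enc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(enc$format, "diffpes-dataset")) {
    stop("not a diffpes dataset archive: ", path)
  }
  systems <- vector("list", length(enc$systems))
  registry <- vector("list", length(enc$systems))
  for (i in seq_along(enc$systems)) {
    rec <- enc$systems[[i]]
    species <- unlist(rec$species)
    bonds <- matrix(as.integer(unlist(rec$bonds)), ncol = 2,
                    byrow = !is.matrix(rec$bonds))
    if (is.matrix(rec$bonds)) bonds <- matrix(as.integer(rec$bonds), ncol = 2)
    angles <- if (length(rec$angles) == 0) matrix(integer(0), ncol = 3) else
      matrix(as.integer(rec$angles), ncol = 3)
    top <- structure(list(n_atoms = length(species), species = species,
                          bonds = bonds, angles = angles),
                     class = "toy_topology")
    ff <- lapply(rec$ff, function(v) if (is.list(v)) unlist(v) else v)
    coords <- matrix(as.numeric(rec$coords), ncol = 3)
    if (identical(enc$style, "quadratic")) {
      d <- 3 * length(species)
      pes <- structure(list(topology = top, style = "quadratic", ff = ff,
                            hessian = matrix(as.numeric(rec$hessian), d, d),
                            x_star = matrix(as.numeric(rec$x_star), ncol = 3)),
                       class = "toy_pes")
      pes$eigenvalues <- eigen(pes$hessian, symmetric = TRUE,
                               only.values = TRUE)$values
    } else {
      pes <- structure(list(topology = top, style = "bonded", ff = ff,
                            rep_pairs = repulsion_pairs(top),
                            x_star = coords),
                       class = "toy_pes")
    }
    pes$energy_unit <- "kcal/mol"
    pes$fmax <- enc$fmax
    systems[[i]] <- atomic_system(species, coords, id = rec$id)
    registry[[i]] <- pes
  }
  names(registry) <- vapply(systems, function(s) s$id, "")
  splits <- lapply(enc$splits, function(v) as.integer(unlist(v)))
  structure(list(systems = systems, pes_registry = registry, splits = splits,
                 seed = enc$seed, fmax = enc$fmax, style = enc$style),
            class = "ground_state_dataset")
}
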