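#' Construct an atomic system
#'
#' An `atomic_system` bundles per-atom species labels with 3D coordinates (in
#' angstrom). It is the object every stage of the pipeline consumes and
#' produces: toy-PES evaluation, diffusion encoding/decoding, chains and
#' benchmarks.
#'
#' @param species character vector of per-atom species labels (small alphabet,
#'   e.g. `"A".."D"` mimicking H/O/N/C).
#' @param coords numeric matrix, `n_atoms x 3`, angstrom.
#' @param id opaque identifier (character).
#' @param charges optional integer vector of formal charges (off by default).
#' @return an object of class `atomic_system`.
#' @export
atomic_system <- function(species, coords, id = "system", charges = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an n x 3 matrix")
  }
  if (length(species) != nrow(coords)) {
    stop("species length must equal the number of coordinate rows")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(charges) && length(charges) != length(species)) {
    stop("charges length must equal species length")
  }
  structure(
    list(species = as.character(species), coords = unname(coords),
         charges = charges, id = as.character(id)),
    class = "atomic_system"
  )
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("<atomic_system '%s': %d atoms (%s)>\n", x$id,
              length(x$species), paste(sort(unique(x$species)), collapse = ",")))
  invisible(x)
}

n_atoms <- function(system) length(system$species)

#' Read structures from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line (key=value pairs
#' such as `id=... energy=...` are parsed into attributes), then one
#' `element x y z` record per atom. Multi-frame files are supported.
#'
#' @param path file path.
#' @return a list of [atomic_system()] objects (possibly of length one).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines))]
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty XYZ file: ", path)
  }
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed atom count at line ", i)
    if (i + 1 + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", i)
    }
    comment <- lines[i + 1]
    rec <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad) > 0) stop("malformed atom record at line ", i + 1 + bad[1])
    species <- vapply(toks, `[[`, "", 1)
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (!all(is.finite(coords))) stop("non-numeric coordinates in frame at line ", i)
    kv <- parse_xyz_comment(comment)
    sys <- atomic_system(species, coords, id = kv[["id"]] %||% "xyz")
    if (!is.null(kv[["energy"]])) attr(sys, "energy") <- as.numeric(kv[["energy"]])
    out[[length(out) + 1]] <- sys
    i <- i + 2 + n
  }
  out
}

parse_xyz_comment <- function(comment) {
  toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- list()
  for (t in toks) {
    parts <- strsplit(t, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2) kv[[parts[1]]] <- parts[2]
  }
  kv
}

#' Write structures to an XYZ file
#'
#' @param systems a single [atomic_system()] or a list of them (multi-frame).
#' @param path output file path.
#' @param energies optional numeric vector written into the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(systems, path, energies = NULL) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(systems)) {
    s <- systems[[k]]
    comment <- sprintf("id=%s", s$id)
    if (!is.null(energies)) comment <- sprintf("%s energy=%.12g", comment, energies[k])
    writeLines(as.character(length(s$species)), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.10f %.10f %.10f", s$species,
                       s$coords[, 1], s$coords[, 2], s$coords[, 3]), con)
  }
  invisible(path)
}
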