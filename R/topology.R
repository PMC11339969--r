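#' Default toy species alphabet
#'
#' Four labels A, B, C, D with maximum valences 1, 2, 3, 4 (mimicking
#' H, O, N, C), covalent-like radii used for bond perception and geometry
#' seeding, and per-species bond stiffness scaling. The alphabet is a plain
#' data.frame so callers can supply their own.
#'
#' @return data.frame with columns `species`, `max_degree`, `radius`.
#' @export
default_alphabet <- function() {
  data.frame(
    species = c("A", "B", "C", "D"),
    max_degree = c(1L, 2L, 3L, 4L),
    radius = c(0.37, 0.66, 0.71, 0.77),
    stringsAsFactors = FALSE
  )
}

alphabet_lookup <- function(alphabet, species, column) {
  idx <- match(species, alphabet$species)
  if (anyNA(idx)) stop("unknown species label: ",
                       paste(unique(species[is.na(idx)]), collapse = ", "))
  alphabet[[column]][idx]
}

#' Sample a random valence-respecting molecular topology
#'
#' Draws a connected bond graph (a random spanning tree) over `n_atoms` atoms
#' whose species are drawn from `alphabet`, respecting each species' maximum
#' degree. Angle triples are derived from the bond list (all pairs of
#' neighbours around each centre). Deterministic given `seed`.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param alphabet species table as from [default_alphabet()]; may be a subset.
#' @param seed integer seed.
#' @return a `toy_topology`: list with `n_atoms`, `species`, `bonds`
#'   (m x 2 integer matrix, i < j), `angles` (k x 3 integer matrix, centre in
#'   column 2).
#' @export
sample_topology <- function(n_atoms, alphabet = default_alphabet(), seed = 0) {
  stopifnot(n_atoms >= 2, nrow(alphabet) >= 1)
  with_seed(seed, {
    for (attempt in 1:200) {
      species <- sample(alphabet$species, n_atoms, replace = TRUE)
      maxdeg <- alphabet_lookup(alphabet, species, "max_degree")
      ## a connected graph needs total degree >= 2*(n-1): every tree edge
      ## consumes one degree at each end
      if (sum(maxdeg) < 2 * (n_atoms - 1)) next
      top <- try(grow_tree(species, maxdeg), silent = TRUE)
      if (!inherits(top, "try-error")) {
        return(finish_topology(species, top))
      }
    }
    ## alphabet may make connectivity impossible (e.g. all max-degree 1)
    if (sum(alphabet$max_degree == max(alphabet$max_degree)) == nrow(alphabet) &&
        max(alphabet$max_degree) * n_atoms < 2 * (n_atoms - 1)) {
      stop("infeasible valence budget: cannot connect ", n_atoms,
           " atoms with the supplied alphabet")
    }
    stop("infeasible valence budget: cannot connect ", n_atoms,
         " atoms with the supplied alphabet")
  })
}

grow_tree <- function(species, maxdeg) {
  n <- length(species)
  deg <- integer(n)
  ## start from the highest-valence atom so chains can branch
  order_in <- order(-maxdeg, sample.int(n))
  placed <- order_in[1]
  bonds <- matrix(integer(0), ncol = 2)
  for (a in order_in[-1]) {
    open <- placed[deg[placed] < maxdeg[placed]]
    if (length(open) == 0 || maxdeg[a] < 1) stop("stuck")
    parent <- if (length(open) == 1) open else sample(open, 1)
    bonds <- rbind(bonds, sort(c(parent, a)))
    deg[parent] <- deg[parent] + 1
    deg[a] <- deg[a] + 1
    placed <- c(placed, a)
  }
  bonds
}

finish_topology <- function(species, bonds) {
  n <- length(species)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  angles <- derive_angles(n, bonds)
  structure(list(n_atoms = n, species = species, bonds = bonds,
                 angles = angles),
            class = "toy_topology")
}

derive_angles <- function(n, bonds) {
  nb <- lapply(seq_len(n), function(i) {
    sort(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  })
  out <- matrix(integer(0), ncol = 3)
  for (j in seq_len(n)) {
    v <- nb[[j]]
    if (length(v) >= 2) {
      pairs <- utils::combn(v, 2)
      out <- rbind(out, cbind(pairs[1, ], j, pairs[2, ]))
    }
  }
  out
}

#' @export
print.toy_topology <- function(x, ...) {
  cat(sprintf("<toy_topology: %d atoms, %d bonds, %d angles>\n",
              x$n_atoms, nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

topology_degrees <- function(topology) {
  tabulate(c(topology$bonds[, 1], topology$bonds[, 2]), topology$n_atoms)
}

topology_connected <- function(topology) {
  n <- topology$n_atoms
  adj <- lapply(seq_len(n), function(i) {
    c(topology$bonds[topology$bonds[, 1] == i, 2],
      topology$bonds[topology$bonds[, 2] == i, 1])
  })
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}
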