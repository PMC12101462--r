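#' Atomic configurations
#'
#' An `atoms` object is the universal structure record of the package: a
#' set of chemical species with per-atom masses, Cartesian positions and,
#' for crystals, a periodic cell.  Gas-phase molecules simply have no cell.
#'
#' @param species character vector of element symbols.
#' @param positions numeric N x 3 matrix of Cartesian positions (Angstrom).
#' @param cell 3 x 3 matrix of row lattice vectors (Angstrom), or `NULL`
#'   for an aperiodic (gas-phase) configuration.
#' @param masses optional numeric vector of per-atom masses (g/mol);
#'   defaults are looked up from [atomic_masses] by species symbol.
#'   Masses are kept per atom so that isotope substitution never touches
#'   the species labels.
#' @param info optional named list of free-form metadata (labels such as
#'   reference energies, provenance tags, comment-line fields).
#' @return an object of class `atoms`.
#' @export
atoms <- function(species, positions, cell = NULL, masses = NULL,
                  info = list()) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) != n)
    stop("species length does not match number of positions")
  if (is.null(masses)) {
    masses <- atomic_masses[species]
    if (anyNA(masses))
      stop("no default mass for species: ",
           paste(unique(species[is.na(masses)]), collapse = ", "))
    masses <- unname(masses)
  }
  masses <- as.numeric(masses)
  if (length(masses) == 1L) masses <- rep(masses, n)
  if (length(masses) != n) stop("masses length does not match atom count")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite")
  if (any(!is.finite(positions))) stop("positions must be finite")
  pbc <- !is.null(cell)
  if (pbc) {
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L))) stop("cell must be a 3 x 3 matrix")
    storage.mode(cell) <- "double"
    if (det(cell) <= 0)
      stop("cell determinant must be positive (right-handed cell)")
  }
  structure(list(species = species, masses = masses, positions = positions,
                 cell = cell, pbc = pbc, info = info),
            class = "atoms")
}

#' @export
print.atoms <- function(x, ...) {
  cat("<atoms> ", n_atoms(x), " atoms (",
      paste(names(table(x$species)), table(x$species), sep = ":",
            collapse = " "), ")",
      if (x$pbc) sprintf(", periodic, V = %.3f A^3", cell_volume(x))
      else ", gas phase", "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config an `atoms` object.
#' @return integer atom count.
#' @export
n_atoms <- function(config) nrow(config$positions)

#' Cell volume of a periodic configuration
#' @param config an `atoms` object with a cell.
#' @return volume in A^3.
#' @export
cell_volume <- function(config) {
  if (!config$pbc) stop("gas-phase configuration has no cell volume")
  det(config$cell)
}

#' Default atomic masses (g/mol)
#'
#' CODATA-rounded standard atomic weights for the light elements that
#' occur in organic molecular crystals, plus deuterium under the symbol
#' "D".  Used when an [atoms] object is built without explicit masses.
#'
#' @export
atomic_masses <- c(H = 1.008, D = 2.014, He = 4.0026, C = 12.011,
                   N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
                   P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948)

#' Replace the masses of one element by an isotope mass
#'
#' Classical configurational averages are independent of nuclear mass, so
#' isotope substitution is a pure relabelling of masses: species symbols,
#' positions and the cell are untouched.  The quantum (path-integral)
#' estimators, by contrast, respond to the mass change, which is what
#' makes H -> D substitution informative about zero-point motion and
#' hydrogen-bond geometry.
#'
#' @param config an `atoms` object.
#' @param element element symbol whose atoms get the new mass.
#' @param new_mass isotope mass in g/mol (e.g. 2.014 for deuterium).
#' @return the modified `atoms` object.  If the element does not occur, the
#'   configuration is returned unchanged with `info$isotope_warning` set
#'   and a warning is raised.
#' @export
substitute_isotope <- function(config, element, new_mass) {
  stopifnot(inherits(config, "atoms"), is.numeric(new_mass), new_mass > 0)
  hit <- config$species == element
  if (!any(hit)) {
    warning("element ", element, " not present; configuration unchanged")
    config$info$isotope_warning <-
      paste0("element ", element, " absent, substitution was a no-op")
    return(config)
  }
  config$masses[hit] <- new_mass
  config
}

#' Replicate a periodic configuration into a supercell
#'
#' Atoms are repeated over integer lattice translations; the cell rows are
#' scaled by the replication counts.  Atom ordering is image-major: all
#' atoms of translation (0,0,0) first, so index `i` of the unit cell maps
#' to index `i` of the supercell.
#'
#' @param config periodic `atoms` object.
#' @param reps integer vector (n1, n2, n3), each >= 1.
#' @return the supercell as an `atoms` object; `info$unit_cell_atoms` and
#'   `info$lattice_translations` record the mapping back to the unit cell.
#' @export
build_supercell <- function(config, reps) {
  stopifnot(inherits(config, "atoms"))
  if (!config$pbc) stop("build_supercell requires a periodic configuration")
  reps <- as.integer(reps)
  if (length(reps) != 3L || any(reps < 1L))
    stop("reps must be three integers >= 1")
  n <- n_atoms(config)
  shifts <- as.matrix(expand.grid(a = 0:(reps[1] - 1),
                                  b = 0:(reps[2] - 1),
                                  c = 0:(reps[3] - 1)))
  # order so that (0,0,0) comes first
  shifts <- shifts[order(shifts[, 3], shifts[, 2], shifts[, 1]), , drop = FALSE]
  ncells <- nrow(shifts)
  disp <- shifts %*% config$cell                  # ncells x 3 Cartesian
  pos <- matrix(0, n * ncells, 3)
  for (ic in seq_len(ncells))
    pos[((ic - 1) * n + 1):(ic * n), ] <-
      sweep(config$positions, 2, disp[ic, ], "+")
  out <- atoms(species = rep(config$species, ncells),
               positions = pos,
               cell = config$cell * matrix(reps, 3, 3),
               masses = rep(config$masses, ncells),
               info = config$info)
  out$info$unit_cell_atoms <- rep(seq_len(n), ncells)
  out$info$lattice_translations <- shifts[rep(seq_len(ncells), each = n), ,
                                          drop = FALSE]
  out
}

#' Minimum-image displacement vectors
#'
#' Displacements `b - a` wrapped into the Wigner-Seitz-like cell obtained
#' by rounding fractional coordinates; exact for separations shorter than
#' half the shortest cell vector of reasonably orthogonal cells.
#'
#' @param dr numeric matrix (M x 3) of raw Cartesian displacements.
#' @param cell 3 x 3 cell matrix, or `NULL` for no wrapping.
#' @return M x 3 matrix of minimum-image displacements.
#' @export
minimum_image <- function(dr, cell) {
  dr <- matrix(dr, ncol = 3)
  if (is.null(cell)) return(dr)
  frac <- dr %*% solve(cell)
  (frac - round(frac)) %*% cell
}

#' Molecular topology
#'
#' Partition of the atoms into molecules plus the intramolecular bond and
#' angle lists used by the toy molecular-crystal potential, and a
#' linearity flag for gas molecules (it decides whether the vibrational
#' degree-of-freedom count is 3N-6 or 3N-5).
#'
#' @param molecule integer vector: molecule index per atom (1-based,
#'   must partition the atom set into 1..M).
#' @param bonds integer matrix (B x 2) of bonded atom pairs, or NULL.
#' @param angles integer matrix (A x 3) of bonded triplets (i-j-k with the
#'   angle at j), or NULL.
#' @param linear logical: is each gas-phase molecule linear?
#' @return an object of class `topology`.
#' @export
topology <- function(molecule, bonds = NULL, angles = NULL, linear = FALSE) {
  molecule <- as.integer(molecule)
  m <- max(molecule)
  if (!setequal(unique(molecule), seq_len(m)))
    stop("molecule indices must partition atoms into 1..M")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > length(molecule)))
      stop("bond indices out of range")
  }
  if (!is.null(angles)) angles <- matrix(as.integer(angles), ncol = 3)
  structure(list(molecule = molecule, n_molecules = m,
                 bonds = bonds, angles = angles, linear = linear),
            class = "topology")
}

#' Degree-of-freedom count for a gas-phase molecule
#' @param n_atoms number of atoms.
#' @param linear logical linearity flag.
#' @return 3N - 6 for non-linear, 3N - 5 for linear molecules.
#' @export
vibrational_dof <- function(n_atoms, linear = FALSE) {
  if (n_atoms < 2) stop("a molecule needs at least two atoms")
  3L * n_atoms - if (linear) 5L else 6L
}
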