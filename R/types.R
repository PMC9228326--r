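# Domain types shared by the builders, engine and analysis: particle
# catalogues, electrostatics configuration, simulation box, bonded topology
# and the full dynamical state. All constructors validate and fail early.

#' Particle type catalogue
#'
#' Named particle species with integer charge valence (elementary-charge
#' units) and reduced mass. Uncharged species have valence 0.
#'
#' @param name character vector of unique short type names.
#' @param valence integer charge per type (may be negative).
#' @param mass reduced DPD mass per type (default 1).
#' @return A `particle_catalog` (data.frame with columns name, valence, mass).
#' @examples
#' particle_catalog(c("H2O", "H2OP", "H2ON"), c(0L, 1L, -1L))
#' @export
particle_catalog <- function(name, valence = integer(length(name)),
                             mass = rep(1, length(name))) {
  if (anyDuplicated(name)) stop("particle type names must be unique")
  if (length(valence) != length(name) || length(mass) != length(name))
    stop("name, valence and mass must have equal length")
  if (any(valence != round(valence)))
    stop("valence must be integer-valued (elementary-charge units)")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("mass must be positive")
  structure(data.frame(name = as.character(name),
                       valence = as.integer(valence),
                       mass = as.numeric(mass),
                       stringsAsFactors = FALSE),
            class = c("particle_catalog", "data.frame"))
}

#' Electrostatics configuration
#'
#' Selects one of the three charge-treatment schemes and its parameters:
#' \describe{
#'   \item{C}{pure Coulomb with the force magnitude truncated at `force_cap`.}
#'   \item{CD}{Coulomb times an exponential charge-smearing term with decay
#'     length `lam`; the force is finite everywhere and vanishes at contact.}
#'   \item{CDS}{CD times an SP3 splitting term approximating periodic mirror
#'     charges; the force and potential vanish smoothly at `cutoff_el`.}
#' }
#' When `lam` is not given it defaults to `gamma` (the decay length equals the
#' coupling constant in reduced DPD length units).
#'
#' @param scheme one of `"C"`, `"CD"`, `"CDS"` (or `"none"` to disable
#'   electrostatics).
#' @param gamma dimensionless coupling constant \eqn{\Gamma > 0}; see
#'   [coupling_constant()].
#' @param lam charge-distribution decay length \eqn{\lambda} in reduced units.
#' @param cutoff_el electrostatic cutoff radius in reduced units (5 or 10 in
#'   typical use; anything positive is accepted).
#' @param force_cap maximum electrostatic force magnitude, applied for scheme
#'   C only (default 25 reduced units).
#' @return An `elec_config` object.
#' @examples
#' elec_config("CD", gamma = coupling_constant(298.15, 4.48))
#' @export
elec_config <- function(scheme = c("CD", "C", "CDS", "none"), gamma = 1,
                        lam = gamma, cutoff_el = 5, force_cap = 25) {
  scheme <- match.arg(scheme)
  for (nm in c("gamma", "lam", "cutoff_el", "force_cap")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("elec_config: '%s' must be a single positive number", nm))
  }
  structure(list(scheme = scheme, gamma = gamma, lam = lam,
                 cutoff_el = cutoff_el, force_cap = force_cap),
            class = "elec_config")
}

#' @export
print.elec_config <- function(x, ...) {
  cat(sprintf(
    "elec_config: scheme %s, Gamma = %.6g, lambda = %.6g, cutoff_el = %g, cap = %g\n",
    x$scheme, x$gamma, x$lam, x$cutoff_el, x$force_cap))
  invisible(x)
}

# internal: scheme code for the C++ kernels (0 none, 1 C, 2 CD, 3 CDS)
scheme_code <- function(cfg) {
  match(cfg$scheme, c("none", "C", "CD", "CDS")) - 1L
}

elec_list <- function(cfg) {
  list(scheme_code = scheme_code(cfg), gamma = cfg$gamma, lam = cfg$lam,
       cutoff_el = cfg$cutoff_el, force_cap = cfg$force_cap)
}

#' Simulation box
#'
#' Orthorhombic box with per-dimension periodicity. Non-periodic dimensions
#' are closed by reflecting boundaries plus a soft repulsive wall (see
#' [run_simulation()]).
#'
#' @param lengths three positive reduced box lengths (Lx, Ly, Lz).
#' @param periodic three logicals; default fully periodic.
#' @return A `simulation_box` object.
#' @export
simulation_box <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  if (length(lengths) != 3 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be three positive numbers")
  if (length(periodic) != 3 || !is.logical(periodic))
    stop("periodic must be three logicals")
  structure(list(lengths = as.numeric(lengths), periodic = periodic),
            class = "simulation_box")
}

#' Bonded topology and molecule membership
#'
#' @param bonds data.frame with columns `i`, `j` (1-based particle indices),
#'   `k` (spring constant) and `r0` (equilibrium length); may have zero rows.
#' @param molecule_id integer molecule membership per particle.
#' @param role character tag per particle (e.g. "water", "ion", "lipid_head",
#'   "lipid_tail", "peptide_backbone").
#' @param n_particles total particle count, used to validate bond indices.
#' @return A `topology` object.
#' @export
topology <- function(bonds = data.frame(i = integer(), j = integer(),
                                        k = numeric(), r0 = numeric()),
                     molecule_id, role, n_particles = length(molecule_id)) {
  stopifnot(is.data.frame(bonds),
            all(c("i", "j", "k", "r0") %in% names(bonds)))
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) stop("topology: self-bonds are not allowed")
    if (any(bonds$i < 1 | bonds$i > n_particles |
            bonds$j < 1 | bonds$j > n_particles))
      stop("topology: bond indices out of range")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("topology: duplicate bonded pair")
    if (any(bonds$k < 0)) stop("topology: spring constants must be >= 0")
  }
  if (length(molecule_id) != n_particles || length(role) != n_particles)
    stop("topology: molecule_id and role must have length n_particles")
  structure(list(bonds = bonds,
                 molecule_id = as.integer(molecule_id),
                 role = as.character(role)),
            class = "topology")
}

#' Dynamical simulation state
#'
#' Positions and velocities in reduced units, per-particle type indices into a
#' [particle_catalog()], the box, the step counter and the RNG seed that
#' governs the thermostat noise. Positions are wrapped into the box along
#' periodic dimensions at construction.
#'
#' @param positions N x 3 numeric matrix (reduced coordinates).
#' @param velocities N x 3 numeric matrix (reduced).
#' @param type_index integer vector of 1-based rows into `catalog`.
#' @param catalog a [particle_catalog()].
#' @param box a [simulation_box()].
#' @param step integer step counter (default 0).
#' @param rng_seed integer seed for the pairwise thermostat noise.
#' @return A `simulation_state` object.
#' @export
simulation_state <- function(positions, velocities, type_index, catalog, box,
                             step = 0L, rng_seed = 1L) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            is.matrix(velocities), ncol(velocities) == 3,
            inherits(catalog, "particle_catalog"),
            inherits(box, "simulation_box"))
  n <- nrow(positions)
  if (nrow(velocities) != n || length(type_index) != n)
    stop("positions, velocities and type_index must agree in length")
  if (any(type_index < 1 | type_index > nrow(catalog)))
    stop("type_index out of catalog range")
  if (any(!is.finite(positions)) || any(!is.finite(velocities)))
    stop("non-finite positions or velocities")
  for (k in 1:3) {
    if (box$periodic[k]) {
      positions[, k] <- positions[, k] %% box$lengths[k]
    } else if (any(positions[, k] < 0 | positions[, k] > box$lengths[k])) {
      stop("positions outside non-periodic box dimension ", k)
    }
  }
  structure(list(positions = positions, velocities = velocities,
                 type_index = as.integer(type_index), catalog = catalog,
                 box = box, step = as.integer(step),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(
    "simulation_state: %d particles, %d types, box %s, step %d\n",
    nrow(x$positions), nrow(x$catalog),
    paste(signif(x$box$lengths, 4), collapse = " x "), x$step))
  tb <- table(x$catalog$name[x$type_index])
  cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# internal: per-particle valences / masses from the catalog
state_valences <- function(state) state$catalog$valence[state$type_index]
state_masses <- function(state) state$catalog$mass[state$type_index]
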