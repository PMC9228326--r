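# Seeded builders for the two experimental systems: the ion-pair water box
# used for RDF / ion-pairing diagnostics, and the toy membrane/peptide
# "sandwich" used for lipid-extraction studies. Builders are pure functions
# of (spec, seed): identical inputs give bitwise-identical systems.

MIN_PLACEMENT_DIST <- 0.01 # non-pair particles never start closer than this

# internal: Maxwell velocities at kBT = 1 with zero total momentum
maxwell_velocities <- function(n, masses) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(1 / masses)), n, 3)
  com <- colSums(v * masses) / sum(masses)
  sweep(v, 2, com)
}

# internal: redraw uniformly-placed particles that violate the minimum
# placement distance (only indices in `movable` may be redrawn)
enforce_min_distance <- function(pos, box, movable, excl_pairs,
                                 max_iter = 50) {
  ei <- excl_pairs$i %||% integer(0)
  ej <- excl_pairs$j %||% integer(0)
  movable <- as.integer(movable)
  for (it in seq_len(max_iter)) {
    cp <- cpp_close_pairs(pos, box$lengths, box$periodic,
                          MIN_PLACEMENT_DIST, ei, ej)
    if (length(cp) == 0) return(pos)
    bad <- unique(intersect(matrix(cp, ncol = 2, byrow = TRUE)[, 2], movable))
    if (length(bad) == 0)
      bad <- unique(intersect(cp, movable))
    if (length(bad) == 0)
      stop("cannot satisfy minimum placement distance: offending pairs are immovable")
    pos[bad, ] <- sapply(box$lengths, function(L)
      stats::runif(length(bad), 0, L))
    if (length(bad) == 1) pos[bad, ] <- matrix(pos[bad, ], 1, 3)
  }
  stop("placement rejection did not converge")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of an ion-pair water box
#'
#' A fully periodic box of water beads containing `n_ion_pairs` monovalent
#' ion pairs (types H2OP/H2ON, valences +1/-1), each pair initially co-located
#' at the same position so that pair separation can serve as an ion-pairing
#' diagnostic. Optional uncharged control pairs (ordinary water beads, also
#' co-located) provide the neutral reference for that diagnostic. The total
#' particle count is set by the box volume times the target density.
#'
#' @param box_lengths three reduced box lengths (default 10 x 10 x 10).
#' @param n_ion_pairs number of +/- ion pairs (each contributes 2 particles).
#' @param n_control_pairs number of co-located uncharged water pairs tracked
#'   alongside the ion pairs (default 0).
#' @param density target number density (must lie in \[2.5, 3.5\]).
#' @param seed integer seed.
#' @return An `ion_water_spec` object.
#' @export
ion_water_spec <- function(box_lengths = c(10, 10, 10), n_ion_pairs = 100,
                           n_control_pairs = 0, density = 3, seed = 1) {
  if (density < 2.5 || density > 3.5)
    stop("invalid spec: density must lie in [2.5, 3.5]")
  n_total <- round(prod(box_lengths) * density)
  n_water <- n_total - 2 * n_ion_pairs
  if (n_ion_pairs < 0 || n_control_pairs < 0 ||
      n_water < 2 * n_control_pairs)
    stop("invalid spec: counts inconsistent with box volume and density")
  structure(list(box_lengths = box_lengths, n_ion_pairs = n_ion_pairs,
                 n_control_pairs = n_control_pairs, n_water = n_water,
                 density = density, seed = as.integer(seed)),
            class = "ion_water_spec")
}

#' Build an ion-pair water box
#'
#' Places particles uniformly at random (seeded), with each ion pair's two
#' partners at identical coordinates and all other particles kept at least
#' 0.01 reduced units apart. Velocities are Maxwell-distributed at
#' \eqn{k_B T = 1} with zero total momentum.
#'
#' @param spec an [ion_water_spec()].
#' @return A list with elements `state` ([simulation_state()]), `topo`
#'   ([topology()]; no bonds), `pair_map` (data.frame `i`, `j`, `charged`
#'   of initially co-located pairs) and `spec`.
#' @export
build_ion_water_box <- function(spec) {
  stopifnot(inherits(spec, "ion_water_spec"))
  set.seed(spec$seed)
  cat_iw <- particle_catalog(c("H2O", "H2OP", "H2ON"), c(0L, 1L, -1L))
  box <- simulation_box(spec$box_lengths)
  np <- spec$n_ion_pairs
  nc <- spec$n_control_pairs
  nw <- spec$n_water
  n <- nw + 2 * np

  # layout: [H2OP x np][H2ON x np][H2O x nw]; pair p = (p, np + p);
  # control pair q = (2np + q, 2np + nc + q)
  type_index <- c(rep(2L, np), rep(3L, np), rep(1L, nw))
  pos <- sapply(box$lengths, function(L) stats::runif(n, 0, L))
  if (np > 0) pos[np + seq_len(np), ] <- pos[seq_len(np), ]
  if (nc > 0) pos[2 * np + nc + seq_len(nc), ] <- pos[2 * np + seq_len(nc), ]

  pair_map <- data.frame(
    i = c(seq_len(np), if (nc > 0) 2 * np + seq_len(nc)),
    j = c(np + seq_len(np), if (nc > 0) 2 * np + nc + seq_len(nc)),
    charged = rep(c(TRUE, FALSE), c(np, nc)))
  pos <- enforce_min_distance(pos, box, movable = seq_len(n),
                              excl_pairs = pair_map)
  # redraws may separate a tracked pair: re-co-locate partners
  if (nrow(pair_map) > 0) pos[pair_map$j, ] <- pos[pair_map$i, ]

  masses <- cat_iw$mass[type_index]
  vel <- maxwell_velocities(n, masses)
  state <- simulation_state(pos, vel, type_index, cat_iw, box,
                            rng_seed = spec$seed)
  topo <- topology(molecule_id = seq_len(n),
                   role = c(rep("ion", 2 * np), rep("water", nw)),
                   n_particles = n)
  list(state = state, topo = topo, pair_map = pair_map, spec = spec)
}

#' Plasma-membrane lipid composition preset (cholesterol-free)
#'
#' Splits a total lipid count into per-class, per-leaflet counts for the
#' five-component phospholipid mixture used for plasma-membrane models
#' without cholesterol: 40% DMPC, 20% DOPE, 5% PIP2, 10% DOPS, 25% SM, with
#' inner:outer leaflet distributions 24:76 (DMPC), 77.5:22.5 (DOPE),
#' 75:25 (PIP2), inner-only DOPS, and 22:78 (SM). Counts are integers by
#' largest-remainder rounding; class totals sum to `total`, and inner + outer
#' sum to each class total. Head-bead valences are toy surrogates: -1 for
#' DOPS, -4 for PIP2, 0 otherwise.
#'
#' @param total total lipid count for one inner + outer leaflet pair.
#' @return data.frame with columns `class`, `total`, `inner`, `outer`,
#'   `head_valence`.
#' @export
preset_nocpm_composition <- function(total) {
  if (total <= 0) stop("total must be > 0")
  frac <- c(DMPC = 0.40, DOPE = 0.20, PIP2 = 0.05, DOPS = 0.10, SM = 0.25)
  inner_share <- c(DMPC = 24 / 100, DOPE = 77.5 / 100, PIP2 = 75 / 100,
                   DOPS = 1, SM = 22 / 100)
  valence <- c(DMPC = 0L, DOPE = 0L, PIP2 = -4L, DOPS = -1L, SM = 0L)
  class_tot <- largest_remainder(frac * total, total)
  inner <- integer(5)
  for (k in seq_len(5)) {
    inner[k] <- largest_remainder(
      c(inner_share[k], 1 - inner_share[k]) * class_tot[k], class_tot[k])[1]
  }
  data.frame(class = names(frac), total = class_tot, inner = inner,
             outer = class_tot - inner, head_valence = unname(valence),
             stringsAsFactors = FALSE)
}

# internal: integer apportionment with largest-remainder rounding
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Specification of a membrane/peptide sandwich system
#'
#' Two preassembled bilayers normal to z near the z-faces of a box periodic in
#' x and y only (reflecting walls in z), enclosing a central water compartment
#' that holds peptide surrogates and counter-ions. Each toy lipid is a head
#' bead (charged per class) bonded to a 4-bead tail (k = 100, r0 = 0.7).
#' The peptide surrogate is a closed ring of backbone beads carrying a
#' hydrophobic patch (beads with reduced repulsion against lipid tails) and
#' optional charged beads giving a configurable net charge.
#'
#' @param box_lengths three reduced lengths; z is the membrane normal.
#' @param composition per-class leaflet counts as returned by
#'   [preset_nocpm_composition()]; the default fills the available membrane
#'   area with that preset.
#' @param area_per_lipid reduced area per lipid in a leaflet (default 1.2).
#' @param n_peptides number of peptide surrogates in the compartment.
#' @param peptide_backbone ring size of the peptide surrogate (default 12).
#' @param peptide_hydrophobic number of hydrophobic patch beads (default 4).
#' @param peptide_charge integer net charge per peptide (default 0; the
#'   charge-state contrast of interest is 0 versus +3).
#' @param density target number density (water fills the remaining volume).
#' @param seed integer seed.
#' @return A `sandwich_spec` object.
#' @export
sandwich_spec <- function(box_lengths = c(8, 8, 24), composition = NULL,
                          area_per_lipid = 1.2, n_peptides = 4,
                          peptide_backbone = 12, peptide_hydrophobic = 4,
                          peptide_charge = 0, density = 3, seed = 1) {
  area <- box_lengths[1] * box_lengths[2]
  n_leaf <- floor(area / area_per_lipid)
  if (is.null(composition)) {
    # the preset's leaflet split is asymmetric; fill the membrane area up to
    # whichever leaflet saturates first
    tot <- 2 * n_leaf
    repeat {
      composition <- preset_nocpm_composition(tot)
      if (sum(composition$inner) <= n_leaf && sum(composition$outer) <= n_leaf)
        break
      tot <- tot - 1
    }
  }
  if (max(composition$inner, composition$outer) > 0 &&
      (sum(composition$inner) > n_leaf || sum(composition$outer) > n_leaf))
    stop("geometric overflow: leaflet counts exceed membrane area at the configured area per lipid")
  if (peptide_hydrophobic > peptide_backbone)
    stop("more hydrophobic patch beads than backbone beads")
  half_thick <- (LIPID_TAIL_BEADS + 0.5) * LIPID_BOND_R0
  if ((1 + half_thick + 0.2) + half_thick >=
      box_lengths[3] - 1 - half_thick - 0.2)
    stop("geometric overflow: box too short in z for two bilayers and a compartment")
  structure(list(box_lengths = box_lengths, composition = composition,
                 area_per_lipid = area_per_lipid, n_peptides = n_peptides,
                 peptide_backbone = as.integer(peptide_backbone),
                 peptide_hydrophobic = as.integer(peptide_hydrophobic),
                 peptide_charge = as.integer(peptide_charge),
                 density = density, seed = as.integer(seed)),
            class = "sandwich_spec")
}

# toy lipid geometry
LIPID_BOND_K <- 100
LIPID_BOND_R0 <- 0.7
LIPID_TAIL_BEADS <- 4L

#' Build a membrane/peptide sandwich system
#'
#' Assembles the system described by a [sandwich_spec()]: two bilayers with
#' their outer leaflets facing the central compartment, peptide surrogates
#' placed randomly in the compartment, counter-ions restoring global charge
#' neutrality, and water filling the remainder at the target density. The
#' conservative repulsion matrix encodes the hydrophobic contrast (water-tail
#' 80, head-tail 50, hydrophobic-patch-tail 15, backbone-tail 60, baseline
#' 25).
#'
#' @param spec a [sandwich_spec()].
#' @return A list with elements `state`, `topo`, `params` (a [dpd_params()]
#'   with the type-pair repulsion matrix), `membranes` (metadata for
#'   [lipid_extraction_trace()]: per-lipid table, bilayer midplanes,
#'   compartment direction) and `spec`.
#' @export
build_sandwich <- function(spec) {
  stopifnot(inherits(spec, "sandwich_spec"))
  set.seed(spec$seed)
  comp <- spec$composition
  L <- spec$box_lengths
  box <- simulation_box(L, periodic = c(TRUE, TRUE, FALSE))

  head_types <- paste0("H_", comp$class)
  cat_names <- c("W", head_types, "T", "PB", "PH", "PQ", "CIP", "CIN")
  pep_q_sign <- if (spec$peptide_charge >= 0) 1L else -1L
  valences <- c(0L, comp$head_valence, 0L, 0L, 0L, pep_q_sign, 1L, -1L)
  cat_sw <- particle_catalog(cat_names, valences)
  nt <- nrow(cat_sw)
  idx_of <- function(nm) match(nm, cat_sw$name)

  # conservative repulsions: hydrophobic/hydrophilic contrast
  aij <- matrix(25, nt, nt, dimnames = list(cat_sw$name, cat_sw$name))
  tails <- "T"
  waterlike <- c("W", head_types, "PQ", "CIP", "CIN")
  aij[waterlike, tails] <- aij[tails, waterlike] <- 80
  aij[head_types, tails] <- aij[tails, head_types] <- 50
  aij["PB", tails] <- aij[tails, "PB"] <- 60
  aij["PH", tails] <- aij[tails, "PH"] <- 15
  aij["PH", "W"] <- aij["W", "PH"] <- 80

  half_thick <- (LIPID_TAIL_BEADS + 0.5) * LIPID_BOND_R0 # head-to-midplane
  zm <- c(1 + half_thick + 0.2, L[3] - 1 - half_thick - 0.2) # midplanes
  if (zm[1] + half_thick >= zm[2] - half_thick)
    stop("geometric overflow: box too short in z for two bilayers")

  pos <- NULL; typ <- integer(0); mol <- integer(0); role <- character(0)
  bonds <- list(); lipid_rows <- list()
  mol_id <- 0L

  leaflet_grid <- function(n) {
    g <- ceiling(sqrt(n))
    xy <- expand.grid(x = (seq_len(g) - 0.5) * L[1] / g,
                      y = (seq_len(g) - 0.5) * L[2] / g)
    xy <- xy[sample.int(nrow(xy), n), , drop = FALSE]
    as.matrix(xy) + matrix(stats::runif(2 * n, -0.05, 0.05), n, 2)
  }

  add_lipid <- function(x, y, head_type, bilayer, leaflet, zmid, dir) {
    # dir: +1 tail beads above head (head below midplane), -1 opposite
    nb <- 1L + LIPID_TAIL_BEADS
    zs <- zmid - dir * (half_thick - LIPID_BOND_R0 * (seq_len(nb) - 1))
    p <- cbind(x + stats::runif(nb, -0.02, 0.02),
               y + stats::runif(nb, -0.02, 0.02), zs)
    i0 <- nrow(pos %||% matrix(0, 0, 3))
    pos <<- rbind(pos, p)
    typ <<- c(typ, idx_of(head_type), rep(idx_of("T"), LIPID_TAIL_BEADS))
    mol_id <<- mol_id + 1L
    mol <<- c(mol, rep(mol_id, nb))
    role <<- c(role, "lipid_head", rep("lipid_tail", LIPID_TAIL_BEADS))
    bonds[[length(bonds) + 1L]] <<- data.frame(
      i = i0 + seq_len(nb - 1), j = i0 + seq_len(nb - 1) + 1,
      k = LIPID_BOND_K, r0 = LIPID_BOND_R0)
    lipid_rows[[length(lipid_rows) + 1L]] <<- data.frame(
      molecule = mol_id, bilayer = bilayer, leaflet = leaflet,
      first_bead = i0 + 1L, n_beads = nb,
      class = sub("^H_", "", head_type))
  }

  for (b in 1:2) {
    # inner leaflet faces the wall, outer faces the compartment centre
    comp_dir <- if (b == 1) +1 else -1
    for (lf in c("inner", "outer")) {
      counts <- if (lf == "inner") comp$inner else comp$outer
      ntot <- sum(counts)
      if (ntot == 0) next
      xy <- leaflet_grid(ntot)
      cls <- rep(seq_len(nrow(comp)), counts)
      # dir = +1 puts the head below the midplane; outer-leaflet heads sit on
      # the compartment side
      head_side <- if (lf == "outer") -comp_dir else comp_dir
      for (q in seq_len(ntot)) {
        add_lipid(xy[q, 1], xy[q, 2], head_types[cls[q]], b, lf,
                  zm[b], dir = head_side)
      }
    }
  }
  lipids <- do.call(rbind, lipid_rows)

  # peptide surrogates: closed backbone ring + hydrophobic patch + charges
  ring_r <- spec$peptide_backbone * LIPID_BOND_R0 / (2 * pi)
  z_comp <- c(zm[1] + half_thick + 1, zm[2] - half_thick - 1)
  n_q <- abs(spec$peptide_charge)
  for (p in seq_len(spec$n_peptides)) {
    cx <- stats::runif(1, ring_r, L[1] - ring_r)
    cy <- stats::runif(1, ring_r, L[2] - ring_r)
    cz <- stats::runif(1, z_comp[1], z_comp[2])
    ang <- 2 * pi * (seq_len(spec$peptide_backbone) - 1) / spec$peptide_backbone
    pb <- cbind(cx + ring_r * cos(ang), cy + ring_r * sin(ang), cz)
    i0 <- nrow(pos)
    nb <- spec$peptide_backbone
    pos <- rbind(pos, pb)
    typ <- c(typ, rep(idx_of("PB"), nb))
    # ring closure
    ij <- cbind(i0 + seq_len(nb), i0 + c(seq_len(nb - 1) + 1, 1))
    bonds[[length(bonds) + 1L]] <- data.frame(i = ij[, 1], j = ij[, 2],
                                              k = LIPID_BOND_K,
                                              r0 = LIPID_BOND_R0)
    mol_id <- mol_id + 1L
    mol <- c(mol, rep(mol_id, nb))
    role <- c(role, rep("peptide_backbone", nb))
    # hydrophobic patch beads attached to consecutive backbone beads
    nh <- spec$peptide_hydrophobic
    if (nh > 0) {
      hb <- pb[seq_len(nh), , drop = FALSE]
      hb[, 3] <- hb[, 3] + 0.5
      ih0 <- nrow(pos)
      pos <- rbind(pos, hb)
      typ <- c(typ, rep(idx_of("PH"), nh))
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = i0 + seq_len(nh), j = ih0 + seq_len(nh),
        k = LIPID_BOND_K, r0 = 0.5)
      mol <- c(mol, rep(mol_id, nh))
      role <- c(role, rep("peptide_hydrophobic", nh))
    }
    # charged side beads on the opposite face
    if (n_q > 0) {
      anchors <- i0 + (seq_len(n_q) - 1) %% nb + 1
      qb <- pb[(seq_len(n_q) - 1) %% nb + 1, , drop = FALSE]
      qb[, 3] <- qb[, 3] - 0.5
      iq0 <- nrow(pos)
      pos <- rbind(pos, qb)
      typ <- c(typ, rep(idx_of("PQ"), n_q))
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = anchors, j = iq0 + seq_len(n_q), k = LIPID_BOND_K, r0 = 0.5)
      mol <- c(mol, rep(mol_id, n_q))
      role <- c(role, rep("peptide_charge", n_q))
    }
  }

  # counter-ions restore global neutrality
  q_total <- sum(cat_sw$valence[typ])
  n_ci <- abs(q_total)
  if (n_ci > 0) {
    ci_type <- if (q_total < 0) idx_of("CIP") else idx_of("CIN")
    ci <- cbind(stats::runif(n_ci, 0, L[1]), stats::runif(n_ci, 0, L[2]),
                stats::runif(n_ci, z_comp[1], z_comp[2]))
    pos <- rbind(pos, ci)
    typ <- c(typ, rep(ci_type, n_ci))
    mol <- c(mol, mol_id + seq_len(n_ci))
    mol_id <- mol_id + n_ci
    role <- c(role, rep("ion", n_ci))
  }

  # water fills to the target density
  n_target <- round(prod(L) * spec$density)
  n_w <- n_target - nrow(pos)
  if (n_w < 0) stop("geometric overflow: structured particles exceed target density")
  if (n_w > 0) {
    # keep initial waters out of the bilayer hydrophobic cores
    draw_z <- function(m) {
      z <- stats::runif(m, 0.3, L[3] - 0.3)
      bad <- abs(z - zm[1]) < 2 | abs(z - zm[2]) < 2
      while (any(bad)) {
        z[bad] <- stats::runif(sum(bad), 0.3, L[3] - 0.3)
        bad <- abs(z - zm[1]) < 2 | abs(z - zm[2]) < 2
      }
      z
    }
    w <- cbind(stats::runif(n_w, 0, L[1]), stats::runif(n_w, 0, L[2]),
               draw_z(n_w))
    i0 <- nrow(pos)
    pos <- rbind(pos, w)
    typ <- c(typ, rep(idx_of("W"), n_w))
    mol <- c(mol, mol_id + seq_len(n_w))
    role <- c(role, rep("water", n_w))
    movable <- i0 + seq_len(n_w)
    pos <- enforce_min_distance(pos, box, movable,
                                excl_pairs = data.frame(i = integer(0),
                                                        j = integer(0)))
  }

  n <- nrow(pos)
  pos[, 3] <- pmin(pmax(pos[, 3], 1e-3), L[3] - 1e-3)
  vel <- maxwell_velocities(n, cat_sw$mass[typ])
  state <- simulation_state(pos, vel, typ, cat_sw, box, rng_seed = spec$seed)
  topo <- topology(do.call(rbind, bonds), mol, role, n_particles = n)
  params <- dpd_params(repulsion = unname(aij))
  membranes <- list(lipids = lipids, midplane_z = zm,
                    compartment_dir = c(+1, -1))
  list(state = state, topo = topo, params = params, membranes = membranes,
       spec = spec)
}
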