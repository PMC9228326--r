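# Shared fixtures: small random systems and pure-R oracles.

# random uncharged/charged mixed system for engine checks
random_system <- function(n = 200, box_lengths = c(6, 6, 6),
                          periodic = c(TRUE, TRUE, TRUE),
                          n_charged = 20, n_bonds = 10, seed = 42) {
  set.seed(seed)
  cat3 <- particle_catalog(c("W", "P", "M"), c(0L, 1L, -1L))
  ty <- c(rep(2L, n_charged %/% 2), rep(3L, n_charged - n_charged %/% 2),
          rep(1L, n - n_charged))
  pos <- sapply(box_lengths, function(L) runif(n, 0, L))
  if (!periodic[3]) pos[, 3] <- runif(n, 0.5, box_lengths[3] - 0.5)
  vel <- matrix(rnorm(3 * n, sd = 1), n, 3)
  vel <- sweep(vel, 2, colMeans(vel)) # zero total momentum
  box <- simulation_box(box_lengths, periodic)
  st <- simulation_state(pos, vel, ty, cat3, box, rng_seed = seed)
  bonds <- if (n_bonds > 0) {
    ij <- matrix(sample.int(n, 2 * n_bonds), ncol = 2)
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    ij <- ij[!duplicated(paste(pmin(ij[, 1], ij[, 2]),
                               pmax(ij[, 1], ij[, 2]))), , drop = FALSE]
    data.frame(i = ij[, 1], j = ij[, 2], k = 4, r0 = 0.7)
  } else {
    data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
  }
  topo <- topology(bonds, molecule_id = seq_len(n),
                   role = rep("water", n), n_particles = n)
  list(state = st, topo = topo)
}

# pure-R minimum-image pair-count oracle for RDF histograms
r_rdf_counts_oracle <- function(frames, box, ia, ib, same, r_max, bin_width) {
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  for (f in seq_len(dim(frames)[3])) {
    p <- frames[, , f]
    for (a in seq_along(ia)) {
      bs <- if (same) seq_along(ib)[-seq_len(a)] else seq_along(ib)
      for (b in bs) {
        i <- ia[a]; j <- ib[b]
        if (!same && i == j) next
        d <- p[i, ] - p[j, ]
        d <- d - box$lengths * round(d / box$lengths) * box$periodic
        r <- sqrt(sum(d^2))
        if (r < r_max) {
          bin <- floor(r / bin_width) + 1
          if (bin <= nbin) counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  counts
}

# constructed extraction fixture with a known linear rate (percent per us).
# n_outer single-bead "lipids" start at the midplane; a fixed number cross
# the threshold per frame and stay there.
extraction_fixture <- function(n_outer = 100, n_frames = 100,
                               frame_us = 0.1, rate_pct_per_us = 5,
                               threshold = 3) {
  um <- unit_mapping(time_per_step_ps = 50)
  emit_every <- frame_us * 1e6 / um$time_per_step_ps
  frames <- array(0, c(n_outer, 3, n_frames))
  lip_per_frame <- rate_pct_per_us * n_outer / 100 * frame_us
  for (f in seq_len(n_frames)) {
    n_out <- floor(lip_per_frame * f)
    if (n_out > 0)
      frames[seq_len(min(n_out, n_outer)), 3, f] <- threshold + 1
  }
  membranes <- list(
    lipids = data.frame(molecule = seq_len(n_outer), bilayer = 1L,
                        leaflet = "outer", first_bead = seq_len(n_outer),
                        n_beads = 1L, class = "DMPC"),
    midplane_z = c(0, 50), compartment_dir = c(+1, -1))
  list(frames = frames, membranes = membranes, um = um,
       emit_every = emit_every)
}
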