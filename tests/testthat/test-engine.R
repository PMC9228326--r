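# DPD force field, thermostat, neighbour search and integration.

test_that("conservative and bond forces have the printed closed forms", {
  expect_equal(conservative_force(25, 1), 0)
  expect_equal(conservative_force(25, 0), 25)
  expect_equal(conservative_force(25, 0.5), 12.5)
  expect_equal(conservative_force(25, 1.7), 0)
  expect_equal(bond_force(4, 1, 1), 0)
  expect_equal(bond_force(4, 1, 1.5), -2) # attractive at extension
  # bond force is the negative gradient of (k/2)(r - r0)^2
  h <- 1e-7
  U <- function(r) 0.5 * 4 * (r - 1)^2
  r <- c(0.6, 1.0, 1.9)
  expect_equal(bond_force(4, 1, r), -(U(r + h) - U(r - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("fluctuation-dissipation is enforced at construction", {
  p <- dpd_params(sigma = 3)
  expect_equal(p$gamma_diss, 4.5)
  expect_error(dpd_params(sigma = 3, gamma_diss = 5),
               "fluctuation-dissipation")
  expect_error(dpd_params(dt = 0), "dt")
  expect_error(dpd_params(repulsion = matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("cell-list forces equal the all-pairs oracle", {
  for (per in list(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))) {
    sys <- random_system(n = 500, box_lengths = c(7, 7, 7), periodic = per,
                         n_charged = 60, n_bonds = 20, seed = 5)
    p <- dpd_params(n_types = 3)
    cfg <- elec_config("CD", gamma = 1.6, cutoff_el = 3)
    f_cell <- compute_forces(sys$state, p, sys$topo, cfg, method = "cell")
    f_brut <- compute_forces(sys$state, p, sys$topo, cfg, method = "brute")
    expect_lt(max(abs(f_cell - f_brut)), 1e-10)
  }
})

test_that("pairwise thermostat conserves momentum over long runs", {
  sys <- random_system(n = 400, n_charged = 40, seed = 3)
  p <- dpd_params(n_types = 3)
  res <- run_simulation(sys$state, 1000, p, sys$topo,
                        elec_config("CD", gamma = 1.6, cutoff_el = 2.5),
                        emit_every = 100)
  drift <- max(abs(as.matrix(res$diagnostics[, c("Px", "Py", "Pz")])))
  expect_lt(drift, 1e-8)
})

test_that("dissipative force vanishes for co-moving particles", {
  sys <- random_system(n = 50, n_charged = 0, n_bonds = 0, seed = 8)
  sys$state$velocities[] <- 1.5 # uniform boost: v_ij = 0 for every pair
  p <- dpd_params(n_types = 3, sigma = 0, gamma_diss = 0) # isolate F^D
  p$gamma_diss <- 4.5; p$sigma <- 0 # dissipative only, no noise
  f_still <- local({
    s <- sys$state; s$velocities[] <- 0
    compute_forces(s, p, sys$topo, thermostat = TRUE)
  })
  f_boost <- compute_forces(sys$state, p, sys$topo, thermostat = TRUE)
  expect_equal(f_boost, f_still, tolerance = 1e-12)
})

test_that("kinetic temperature holds at target within the known dt artifact", {
  sys <- build_ion_water_box(ion_water_spec(box_lengths = c(8, 8, 8),
                                            n_ion_pairs = 0, seed = 7))
  res04 <- run_simulation(sys$state, 3000, dpd_params(dt = 0.04), sys$topo,
                          emit_every = 50)
  kt04 <- mean(res04$diagnostics$kT[res04$diagnostics$step > 500])
  expect_lt(abs(kt04 - 1), 0.03)
  res01 <- run_simulation(sys$state, 6000, dpd_params(dt = 0.01), sys$topo,
                          emit_every = 100)
  kt01 <- mean(res01$diagnostics$kT[res01$diagnostics$step > 2000])
  expect_lt(abs(kt01 - 1), 0.01)
})

test_that("identical seeds give bitwise-identical trajectories", {
  sys <- random_system(n = 150, n_charged = 20, seed = 11)
  p <- dpd_params(n_types = 3)
  cfg <- elec_config("CDS", gamma = 1.6, cutoff_el = 2.5)
  r1 <- run_simulation(sys$state, 200, p, sys$topo, cfg, emit_every = 50)
  r2 <- run_simulation(sys$state, 200, p, sys$topo, cfg, emit_every = 50)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$state$positions, r2$state$positions)
  # a different thermostat seed gives a different trajectory
  sys$state$rng_seed <- 12L
  r3 <- run_simulation(sys$state, 200, p, sys$topo, cfg, emit_every = 50)
  expect_false(identical(r1$frames, r3$frames))
})

test_that("zero forces and velocities leave the state unchanged", {
  cat1 <- particle_catalog("W")
  box <- simulation_box(c(5, 5, 5))
  pos <- rbind(c(1, 1, 1), c(3.5, 3.5, 3.5)) # beyond every cutoff
  st <- simulation_state(pos, matrix(0, 2, 3), c(1L, 1L), cat1, box)
  topo <- topology(molecule_id = 1:2, role = c("water", "water"),
                   n_particles = 2)
  st2 <- integrate_step(st, dpd_params(), topo, thermostat = FALSE)
  expect_equal(st2$positions, pos)
  expect_equal(st2$step, 1L)
  # n_steps = 0 is the identity
  r0 <- run_simulation(st, 0, dpd_params(), topo)
  expect_equal(r0$state$positions, pos)
})

test_that("bonded dimer conserves energy without the thermostat", {
  cat1 <- particle_catalog("W")
  box <- simulation_box(c(10, 10, 10))
  pos <- rbind(c(5, 5, 5), c(5, 5, 5.9))
  st <- simulation_state(pos, matrix(0, 2, 3), c(1L, 1L), cat1, box)
  topo <- topology(data.frame(i = 1, j = 2, k = 4, r0 = 0.7),
                   1:2, c("a", "b"), 2)
  p <- dpd_params(dt = 0.01)
  energy <- function(s) {
    r <- sqrt(sum((s$positions[1, ] - s$positions[2, ])^2))
    ke <- 0.5 * sum(s$velocities^2)
    pe <- 0.5 * 4 * (r - 0.7)^2 + if (r < 1) 0.5 * 25 * (1 - r)^2 else 0
    ke + pe
  }
  e0 <- energy(st)
  s <- st
  for (i in 1:10) s <- run_simulation(s, 100, p, topo,
                                      thermostat = FALSE)$state
  expect_lt(abs(energy(s) - e0) / e0, 1e-3)
})

test_that("reflecting walls keep every particle inside the box", {
  sys <- random_system(n = 300, box_lengths = c(6, 6, 6),
                       periodic = c(TRUE, TRUE, FALSE), n_charged = 30,
                       seed = 13)
  res <- run_simulation(sys$state, 500, dpd_params(n_types = 3), sys$topo,
                        elec_config("CD", gamma = 1.6, cutoff_el = 2.5),
                        emit_every = 50)
  z <- res$frames[, 3, ]
  expect_true(all(z >= 0 & z <= 6))
  expect_true(all(res$state$positions[, 3] >= 0 &
                    res$state$positions[, 3] <= 6))
})

test_that("divergent integration raises an error naming the step", {
  cat1 <- particle_catalog("W")
  box <- simulation_box(c(5, 5, 5))
  pos <- rbind(c(1, 1, 1), c(1, 1, 1.5))
  st <- simulation_state(pos, matrix(0, 2, 3), c(1L, 1L), cat1, box)
  topo <- topology(data.frame(i = 1, j = 2, k = 1e308, r0 = 100),
                   1:2, c("a", "b"), 2)
  expect_error(run_simulation(st, 10, dpd_params(), topo, emit_every = 0),
               "diverged.*step")
})
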