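# Potentials and forces of the three charge-treatment schemes.

test_that("Coulomb term: closed forms and 1/r scaling", {
  expect_equal(coulomb_term(1, 1, 1, 1), 1.0)
  expect_equal(coulomb_term(0.5, 1, -1, 1), -2.0)
  r <- c(0.3, 0.9, 2.1)
  expect_equal(coulomb_term(2 * r, 1, 1, 1.6), coulomb_term(r, 1, 1, 1.6) / 2)
  expect_error(coulomb_term(0, 1, 1, 1), "singular")
})

test_that("charge-distribution term: closed forms and limits", {
  expect_equal(charge_distribution_term(0, 1), 0)
  lam <- 1.37
  expect_equal(charge_distribution_term(lam, lam), 1 - 2 * exp(-2),
               tolerance = 1e-14)
  expect_equal(charge_distribution_term(100, 1), 1, tolerance = 1e-12)
  r <- seq(0, 5, by = 0.05)
  v <- charge_distribution_term(r, 0.8)
  expect_true(all(v >= 0 & v < 1))
  expect_true(all(diff(v) > 0)) # monotone rise from contact
  expect_error(charge_distribution_term(1, -1), "lam")
})

test_that("splitting term: closed forms, exact zero at the cutoff", {
  Rc <- 5
  expect_equal(splitting_term(0, Rc), 1)
  expect_lt(abs(splitting_term(Rc, Rc)), 1e-12)
  expect_equal(splitting_term(Rc / 2, Rc), 51 / 256, tolerance = 1e-14)
  # derivative also vanishes at the cutoff (smooth truncation)
  expect_lt(abs(dpdcharge:::d_splitting_term(Rc, Rc)), 1e-12)
  expect_error(splitting_term(6, 5), "cutoff")
})

test_that("potential is the product of active terms with finite CD contact limit", {
  gam <- 1.3
  cd <- elec_config("CD", gamma = gam, lam = 1)
  expect_equal(electrostatic_potential(cd, 1e-13, 1, 1), gam / 1,
               tolerance = 1e-9)
  cds <- elec_config("CDS", gamma = gam, cutoff_el = 5)
  r <- c(0.5, 2, 4.9)
  expect_equal(electrostatic_potential(cds, r, 1, -1),
               coulomb_term(r, 1, -1, gam) *
                 charge_distribution_term(r, gam) * splitting_term(r, 5))
  # beyond the cutoff everything is zero
  cc <- elec_config("C", gamma = gam, cutoff_el = 5)
  expect_equal(electrostatic_potential(cc, 7, 1, 1), 0)
  expect_equal(electrostatic_force(cc, 7, 1, 1), 0)
})

test_that("CDS converges to CD as the electrostatic cutoff grows", {
  r <- seq(0.1, 4, by = 0.1)
  cd <- elec_config("CD", gamma = 1, lam = 1)
  cds_big <- elec_config("CDS", gamma = 1, lam = 1, cutoff_el = 1e6)
  expect_equal(electrostatic_potential(cds_big, r, 1, 1),
               electrostatic_potential(cd, r, 1, 1), tolerance = 1e-5)
  # and CDS(10) tracks CD more closely than CDS(5), pointwise
  cds5 <- elec_config("CDS", gamma = 1, lam = 1, cutoff_el = 5)
  cds10 <- elec_config("CDS", gamma = 1, lam = 1, cutoff_el = 10)
  fcd <- electrostatic_force(cd, r, 1, 1)
  d5 <- abs(electrostatic_force(cds5, r, 1, 1) - fcd)
  d10 <- abs(electrostatic_force(cds10, r, 1, 1) - fcd)
  # closer agreement overall (strict pointwise ordering breaks only where
  # the CDS5 curve incidentally crosses CD)
  expect_lt(max(d10), max(d5))
  expect_lt(mean(d10), mean(d5))
})

test_that("force closed forms: C cap, CD contact zero, CDS contact limit", {
  cc <- elec_config("C", gamma = 1, cutoff_el = 5, force_cap = 25)
  expect_equal(electrostatic_force(cc, 0.5, 1, 1), 4.0)     # Gamma/r^2
  expect_equal(electrostatic_force(cc, 0.1, 1, 1), 25)      # capped
  expect_equal(electrostatic_force(cc, 0.1, 1, -1), -25)    # attractive cap
  expect_equal(electrostatic_force(cc, 0, 1, -1), -25)      # degenerate r = 0
  cd <- elec_config("CD", gamma = 2, lam = 1.5)
  expect_equal(electrostatic_force(cd, 0, 1, 1), 0)
  gam <- 1.7; lam <- 0.9; Rc <- 5
  cds <- elec_config("CDS", gamma = gam, lam = lam, cutoff_el = Rc)
  expect_equal(electrostatic_force(cds, 0, 1, 1),
               7 * gam / (4 * lam * Rc), tolerance = 1e-12)
  expect_equal(electrostatic_force(cds, 0, 2, -1),
               -2 * 7 * gam / (4 * lam * Rc), tolerance = 1e-12)
})

test_that("force equals the numerical derivative of the potential", {
  h <- 1e-6
  grid <- seq(0.3, 4.5, by = 0.15)
  for (scheme in c("C", "CD", "CDS")) {
    cfg <- elec_config(scheme, gamma = 1.6, cutoff_el = 5)
    # exclude the C-scheme cap region (|F| = Gamma/r^2 > 25 below ~0.25)
    g <- if (scheme == "C") grid[grid > sqrt(1.6 / 25) + 0.05] else grid
    for (zz in list(c(1, 1), c(1, -1), c(2, -1))) {
      num <- -(electrostatic_potential(cfg, g + h, zz[1], zz[2]) -
                 electrostatic_potential(cfg, g - h, zz[1], zz[2])) / (2 * h)
      ana <- electrostatic_force(cfg, g, zz[1], zz[2])
      expect_equal(ana, num, tolerance = 1e-6)
    }
  }
})

test_that("like charges repel everywhere in range, for every scheme", {
  r <- seq(0.001, 4.999, by = 0.01)
  for (scheme in c("C", "CD", "CDS")) {
    cfg <- elec_config(scheme, gamma = 1.6, cutoff_el = 5)
    expect_true(all(electrostatic_force(cfg, r, 1, 1) >= 0))
  }
})

test_that("force curves have the documented shapes", {
  cc <- elec_config("C", gamma = 1, cutoff_el = 5, force_cap = 25)
  tab <- force_curve(cc, seq(0.25, 5, by = 0.01))
  expect_true(all(diff(tab$F) < 0)) # strictly decreasing past the cap radius
  cd <- elec_config("CD", gamma = 1, lam = 1)
  tc <- force_curve(cd, seq(0, 5, by = 1e-3))
  expect_equal(tc$F[1], 0)
  # single interior maximum: one sign change in the finite differences
  sgn <- sign(diff(tc$F))
  flips <- sum(diff(sgn[sgn != 0]) != 0)
  expect_equal(flips, 1)
  expect_gt(tc$r[which.max(tc$F)], 0)
  # TSV output with the documented header
  f <- tempfile(fileext = ".tsv")
  force_curve(cd, c(0, 1, 2), file = f)
  expect_identical(readLines(f, n = 1), "r\tF")
  expect_equal(nrow(utils::read.delim(f)), 3)
})

test_that("newton's third law holds exactly for pair forces in the engine", {
  for (scheme in c("C", "CD", "CDS")) {
    sys <- random_system(n = 60, n_charged = 30, n_bonds = 5, seed = 9)
    cfg <- elec_config(scheme, gamma = 1.6, cutoff_el = 2.5)
    f <- compute_forces(sys$state, dpd_params(n_types = 3), sys$topo, cfg,
                        thermostat = TRUE)
    expect_lt(max(abs(colSums(f))), 1e-10)
  }
})
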