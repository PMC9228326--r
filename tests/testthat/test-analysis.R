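# RDF machinery, pairing diagnostics, extraction rate, kinetic temperature.

test_that("ideal-gas frames give a flat g(r) with correct normalization", {
  set.seed(31)
  n <- 600; nf <- 25
  box <- simulation_box(c(8, 8, 8))
  frames <- array(runif(n * 3 * nf, 0, 8), c(n, 3, nf))
  rdf <- radial_distribution(frames, box, list(all = seq_len(n)), r_max = 4)
  ok <- rdf$counts$all >= 200
  expect_true(all(abs(rdf$g$all[ok] - 1) < 3 / sqrt(rdf$counts$all[ok])))
  expect_lt(abs(mean(rdf$g$all[ok]) - 1), 0.01)
  # integral of g rho 4 pi r^2 dr recovers the mean partner count in range
  rho_b <- (n - 1) / prod(box$lengths)
  integral <- sum(rdf$g$all * rho_b * 4 * pi * rdf$r^2 * rdf$bin_width)
  expected <- rho_b * 4 / 3 * pi * 4^3
  expect_lt(abs(integral - expected) / expected, 0.02)
})

test_that("two fixed particles occupy exactly one bin at their separation", {
  box <- simulation_box(c(10, 10, 10))
  frames <- array(0, c(2, 3, 1))
  frames[1, , 1] <- c(5, 5, 5)
  frames[2, , 1] <- c(5, 5, 7.13)
  rdf <- radial_distribution(frames, box, list(pair = 1:2), r_max = 4,
                             bin_width = 0.05)
  expect_equal(sum(rdf$counts$pair), 1)
  expect_equal(rdf$r[which(rdf$counts$pair == 1)], 2.125) # bin of r = 2.13
})

test_that("histogram matches a pure-R minimum-image oracle exactly", {
  set.seed(17)
  n <- 120; nf <- 3
  box <- simulation_box(c(6, 6, 6), periodic = c(TRUE, TRUE, FALSE))
  frames <- array(runif(n * 3 * nf, 0, 6), c(n, 3, nf))
  ia <- 1:50; ib <- 40:120
  cpp <- dpdcharge:::cpp_rdf_counts(frames, dim(frames), ia, ib, FALSE,
                                    box$lengths, box$periodic, 3, 0.1)
  oracle <- r_rdf_counts_oracle(frames, box, ia, ib, FALSE, 3, 0.1)
  expect_equal(as.numeric(cpp), oracle)
  # like-pair path
  cpp2 <- dpdcharge:::cpp_rdf_counts(frames, dim(frames), ia, ia, TRUE,
                                     box$lengths, box$periodic, 3, 0.1)
  oracle2 <- r_rdf_counts_oracle(frames, box, ia, ia, TRUE, 3, 0.1)
  expect_equal(as.numeric(cpp2), oracle2)
})

test_that("r_max beyond the half box is rejected", {
  box <- simulation_box(c(6, 6, 6))
  frames <- array(runif(30), c(5, 3, 2))
  expect_error(radial_distribution(frames, box, list(a = 1:5), r_max = 4),
               "half the smallest box length")
})

test_that("product check: identical curves give zero residual, missing curve errors", {
  set.seed(5)
  n <- 200; nf <- 30
  box <- simulation_box(c(7, 7, 7))
  frames <- array(runif(n * 3 * nf, 0, 7), c(n, 3, nf))
  idx <- seq_len(n)
  rdf <- radial_distribution(frames, box,
                             list(unlike = list(idx[1:100], idx[101:200]),
                                  like = idx[1:100], reference = idx),
                             r_max = 3)
  # replace curves by one shared curve: residual must vanish identically
  rdf$g$unlike <- rdf$g$like <- rdf$g$reference
  rdf$counts$unlike <- rdf$counts$like <- rdf$counts$reference
  pc <- rdf_product_check(rdf)
  expect_equal(pc$max_residual, 0)
  rdf$g$like <- NULL
  expect_error(rdf_product_check(rdf), "missing curve")
})

test_that("pair distance trace starts at zero and grows for free diffusion", {
  sys <- build_ion_water_box(ion_water_spec(n_ion_pairs = 0,
                                            n_control_pairs = 50, seed = 12))
  frames0 <- array(sys$state$positions, c(nrow(sys$state$positions), 3, 1))
  tr0 <- ion_pair_distance_trace(frames0, sys$state$box, sys$pair_map)
  expect_equal(tr0$mean_dist, 0) # co-located by construction
  res <- run_simulation(sys$state, 1500, dpd_params(n_types = 3), sys$topo,
                        emit_every = 150)
  tr <- ion_pair_distance_trace(res$frames, sys$state$box, sys$pair_map)
  d <- tr$mean_dist[tr$group == "uncharged"]
  # diffusive growth: averaged early window below averaged late window
  expect_lt(mean(d[1:3]), mean(d[8:10]))
  expect_gt(d[1], 0)
})

test_that("extraction estimator recovers a constructed 5 %/us fixture", {
  fx <- extraction_fixture(rate_pct_per_us = 5)
  et <- lipid_extraction_trace(fx$frames, fx$membranes, fx$um,
                               emit_every = fx$emit_every)
  expect_lt(abs(et$rate_pct_per_us - 5) / 5, 0.01)
  expect_equal(et$n_outer, 100)
  # static trajectory: rate 0
  fx0 <- extraction_fixture(rate_pct_per_us = 0)
  et0 <- lipid_extraction_trace(fx0$frames, fx0$membranes, fx0$um,
                                emit_every = fx0$emit_every)
  expect_equal(et0$rate_pct_per_us, 0)
  expect_true(all(et0$trace$percent == 0))
})

test_that("extraction rate is invariant to lipid class relabeling", {
  fx <- extraction_fixture(rate_pct_per_us = 8)
  et1 <- lipid_extraction_trace(fx$frames, fx$membranes, fx$um,
                                emit_every = fx$emit_every)
  fx$membranes$lipids$class <- sample(c("SM", "DOPE", "PIP2"),
                                      nrow(fx$membranes$lipids),
                                      replace = TRUE)
  et2 <- lipid_extraction_trace(fx$frames, fx$membranes, fx$um,
                                emit_every = fx$emit_every)
  expect_equal(et1$rate_pct_per_us, et2$rate_pct_per_us)
})

test_that("extraction respects the persistence requirement", {
  # a lipid that flickers past the threshold for single frames never counts
  fx <- extraction_fixture(n_outer = 10, n_frames = 20, rate_pct_per_us = 0)
  fx$frames[1, 3, seq(1, 20, by = 2)] <- 5 # alternate frames only
  et <- lipid_extraction_trace(fx$frames, fx$membranes, fx$um,
                               emit_every = fx$emit_every, persistence = 2)
  expect_true(all(et$trace$percent == 0))
})

test_that("kinetic temperature estimator is unbiased and boost-invariant", {
  set.seed(77)
  v <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(abs(kinetic_temperature(v) - 1), 0.02)
  boosted <- sweep(v, 2, c(3, -1, 0.5), "+")
  expect_equal(kinetic_temperature(boosted), kinetic_temperature(v),
               tolerance = 1e-12)
  expect_equal(kinetic_temperature(matrix(0, 10, 3)), 0)
  expect_error(kinetic_temperature(matrix(0, 1, 3)), "N > 1")
})

test_that("analyses are pure functions of frames and metadata", {
  set.seed(2)
  frames <- array(runif(90 * 3 * 4, 0, 6), c(90, 3, 4))
  box <- simulation_box(c(6, 6, 6))
  r1 <- radial_distribution(frames, box, list(a = 1:90), r_max = 3)
  r2 <- radial_distribution(frames, box, list(a = 1:90), r_max = 3)
  expect_identical(r1$g, r2$g)
})
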