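# Trajectory analysis: radial distribution functions with the ion-pairing
# product-law diagnostic, the ion-pair distance trace, the lipid-extraction
# rate, and the kinetic-temperature estimator. All analyses are pure
# functions of frames + metadata.

#' Radial distribution functions over a frame stack
#'
#' Minimum-image pair-distance histograms normalized by the ideal-gas shell
#' expectation at the observed partial densities, averaged over frames. For a
#' label given as a single index vector the like-pair g(r) is computed (each
#' unordered pair once); a list of two index vectors gives the cross-pair
#' g(r).
#'
#' @param frames N x 3 x n_frames array of positions (reduced units), as
#'   returned by [run_simulation()].
#' @param box a [simulation_box()].
#' @param pairs named list of labels; each element either an index vector
#'   (like pairs) or a list of two index vectors (cross pairs).
#' @param r_max histogram range; must not exceed half the smallest box length.
#' @param bin_width histogram bin width (default 0.05).
#' @return An `rdf_result`: list with `r` (bin centres), `g` (data.frame of
#'   g(r) per label), `counts` (raw pair counts per bin per label),
#'   `n_frames`, `bin_width`.
#' @export
radial_distribution <- function(frames, box, pairs, r_max = 4,
                                bin_width = 0.05) {
  stopifnot(inherits(box, "simulation_box"), is.array(frames),
            length(dim(frames)) == 3)
  if (r_max > min(box$lengths) / 2)
    stop("r_max must be <= half the smallest box length (minimum image)")
  nf <- dim(frames)[3]
  if (nf < 1) stop("need at least one frame")
  n <- dim(frames)[1]
  nbin <- ceiling(r_max / bin_width)
  edges <- (0:nbin) * bin_width
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  V <- prod(box$lengths)

  g <- list(); counts <- list()
  for (lab in names(pairs)) {
    p <- pairs[[lab]]
    if (is.list(p)) {
      ia <- as.integer(p[[1]]); ib <- as.integer(p[[2]]); same <- FALSE
      npairs <- length(ia) * length(ib) - length(intersect(ia, ib))
    } else {
      ia <- ib <- as.integer(p); same <- TRUE
      npairs <- length(ia) * (length(ia) - 1) / 2
    }
    if (npairs == 0) stop("label '", lab, "' defines no pairs")
    ct <- cpp_rdf_counts(frames, dim(frames), ia, ib, same, box$lengths,
                         box$periodic, r_max, bin_width)
    expected <- nf * npairs * shell_vol / V
    g[[lab]] <- ct / expected
    counts[[lab]] <- ct
  }
  structure(list(r = edges[-1] - bin_width / 2,
                 g = as.data.frame(g, check.names = FALSE),
                 counts = as.data.frame(counts, check.names = FALSE),
                 n_frames = nf, bin_width = bin_width),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins (width %g) x %d labels, %d frames\n",
              length(x$r), x$bin_width, ncol(x$g), x$n_frames))
  invisible(x)
}

#' Ion-pairing product-law residual
#'
#' For a charge-symmetric electrolyte the RDFs should satisfy
#' \eqn{g_{+-}(r)\, g_{--}(r) = g^2(r)} with \eqn{g} the RDF of the uncharged
#' reference fluid. Computes the per-bin residual
#' \eqn{|g_{+-} g_{--} - g^2|} and its maximum over bins with adequate
#' sampling. Violations at contact distances diagnose statistical ion
#' pairing (the pure truncated-Coulomb artifact).
#'
#' @param rdf an `rdf_result` containing the three labelled curves.
#' @param unlike,like,reference label names of the +/-, -/- and uncharged
#'   reference curves.
#' @param min_counts minimum raw pair count per bin (in every curve) for the
#'   bin to enter the maximum (default 500).
#' @return A list: `residual` (data.frame r, residual, well_sampled),
#'   `max_residual` (over well-sampled bins).
#' @export
rdf_product_check <- function(rdf, unlike = "unlike", like = "like",
                              reference = "reference", min_counts = 500) {
  stopifnot(inherits(rdf, "rdf_result"))
  for (lab in c(unlike, like, reference))
    if (!lab %in% names(rdf$g))
      stop("rdf_product_check: missing curve '", lab, "'")
  res <- abs(rdf$g[[unlike]] * rdf$g[[like]] - rdf$g[[reference]]^2)
  ok <- rdf$counts[[unlike]] >= min_counts &
    rdf$counts[[like]] >= min_counts &
    rdf$counts[[reference]] >= min_counts
  if (!any(ok)) stop("no bin reaches the sampling threshold")
  list(residual = data.frame(r = rdf$r, residual = res, well_sampled = ok),
       max_residual = max(res[ok]))
}

#' Ion-pair separation trace
#'
#' Tracks the minimum-image distance between originally co-located particle
#' pairs over a trajectory: the tuning diagnostic for the truncated-Coulomb
#' scheme (pair separations of charged pairs should match those of uncharged
#' control pairs when the coupling is correctly tuned).
#'
#' @param frames N x 3 x n_frames position array.
#' @param box a [simulation_box()].
#' @param pair_map data.frame with columns `i`, `j`, `charged` from
#'   [build_ion_water_box()].
#' @return data.frame with one row per frame and group: `frame`, `group`
#'   ("charged"/"uncharged"), `mean_dist`, `q25`, `q50`, `q75`.
#' @export
ion_pair_distance_trace <- function(frames, box, pair_map) {
  stopifnot(is.array(frames), nrow(pair_map) > 0)
  nf <- dim(frames)[3]
  out <- list()
  for (grp in unique(pair_map$charged)) {
    pm <- pair_map[pair_map$charged == grp, ]
    rows <- lapply(seq_len(nf), function(f) {
      d <- cpp_pair_distances(frames[, , f], pm$i, pm$j, box$lengths,
                              box$periodic)
      q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(frame = f, group = if (grp) "charged" else "uncharged",
                 mean_dist = mean(d), q25 = q[1], q50 = q[2], q75 = q[3])
    })
    out[[length(out) + 1]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Lipid extraction trace and disruption rate
#'
#' Quantifies membrane disruption as the percentage of outer-leaflet lipids
#' extracted into the central compartment over time. A lipid counts as
#' extracted in a frame when its centre of geometry lies farther than
#' `threshold` from its source bilayer's midplane toward the compartment for
#' at least `persistence` consecutive emitted frames. The disruption rate is
#' the least-squares slope of the percentage over an intermediate "linear
#' range" window of the trajectory, reported in percent per microsecond.
#'
#' @param frames N x 3 x n_frames position array.
#' @param membranes membrane metadata from [build_sandwich()] (`lipids`
#'   table, `midplane_z`, `compartment_dir`).
#' @param um a [unit_mapping()] (converts steps to microseconds).
#' @param emit_every steps between emitted frames.
#' @param threshold extraction distance from the midplane, reduced units
#'   (default 3).
#' @param persistence consecutive frames required beyond the threshold
#'   (default 2).
#' @param window fractions of the trajectory bounding the linear-range fit
#'   (default c(0.1, 0.6)).
#' @return An `extraction_trace`: list with `trace` (data.frame time_us,
#'   percent), `rate_pct_per_us`, `window_us`, `n_outer`.
#' @export
lipid_extraction_trace <- function(frames, membranes, um, emit_every,
                                   threshold = 3, persistence = 2,
                                   window = c(0.1, 0.6)) {
  stopifnot(inherits(um, "unit_mapping"), is.array(frames))
  if (is.null(membranes$lipids) || is.null(membranes$midplane_z))
    stop("membrane metadata (lipids, midplane_z) is required")
  lip <- membranes$lipids[membranes$lipids$leaflet == "outer", ]
  if (nrow(lip) == 0) stop("no outer-leaflet lipids in metadata")
  nf <- dim(frames)[3]

  beyond <- matrix(FALSE, nrow(lip), nf)
  for (f in seq_len(nf)) {
    z <- frames[, 3, f]
    for (q in seq_len(nrow(lip))) {
      beads <- lip$first_bead[q] + seq_len(lip$n_beads[q]) - 1L
      cog <- mean(z[beads])
      b <- lip$bilayer[q]
      disp <- (cog - membranes$midplane_z[b]) * membranes$compartment_dir[b]
      beyond[q, f] <- disp > threshold
    }
  }
  # persistence: extracted at f if beyond for the last `persistence` frames
  extracted <- matrix(FALSE, nrow(lip), nf)
  if (nf >= persistence) {
    streak <- integer(nrow(lip))
    for (f in seq_len(nf)) {
      streak <- ifelse(beyond[, f], streak + 1L, 0L)
      extracted[, f] <- streak >= persistence
    }
  }
  pct <- 100 * colSums(extracted) / nrow(lip)
  time_us <- steps_to_microseconds(um, seq_len(nf) * emit_every)

  sel <- time_us >= window[1] * max(time_us) &
    time_us <= window[2] * max(time_us)
  rate <- if (sum(sel) >= 2) {
    unname(stats::coef(stats::lm(pct[sel] ~ time_us[sel]))[2])
  } else NA_real_
  structure(list(trace = data.frame(time_us = time_us, percent = pct),
                 rate_pct_per_us = rate,
                 window_us = range(time_us[sel]),
                 n_outer = nrow(lip)),
            class = "extraction_trace")
}

#' @export
print.extraction_trace <- function(x, ...) {
  cat(sprintf(
    "extraction_trace: %d outer-leaflet lipids, rate %.3g %%/us over [%.3g, %.3g] us\n",
    x$n_outer, x$rate_pct_per_us, x$window_us[1], x$window_us[2]))
  invisible(x)
}

#' Instantaneous kinetic temperature
#'
#' \eqn{k_B T = \sum_i m_i |v_i - \bar v|^2 / (3N - 3)}, accounting for the
#' three degrees of freedom removed with the centre-of-mass momentum.
#'
#' @param x a [simulation_state()], or an N x 3 velocity matrix.
#' @param masses per-particle masses (ignored when `x` is a state).
#' @return Reduced kinetic temperature estimate.
#' @export
kinetic_temperature <- function(x, masses = NULL) {
  if (inherits(x, "simulation_state")) {
    v <- x$velocities
    masses <- state_masses(x)
  } else {
    v <- x
    if (is.null(masses)) masses <- rep(1, nrow(v))
  }
  n <- nrow(v)
  if (n <= 1) stop("kinetic temperature needs N > 1")
  com <- colSums(v * masses) / sum(masses)
  v <- sweep(v, 2, com)
  sum(masses * rowSums(v^2)) / (3 * n - 3)
}
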