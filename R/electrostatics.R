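# Electrostatic potentials and forces for the three charge-treatment schemes.
# The pair potential factorizes as U_E(r) = tC(r) * tD(r) * tS(r); schemes
# omit factors by setting them to one: C uses tC alone (force truncated at a
# cap), CD adds the charge-distribution term tD, CDS additionally the SP3
# splitting term tS. All quantities are in reduced DPD units.

#' Coulomb term of the electrostatic pair potential
#'
#' \eqn{t_C(r) = \Gamma Z_i Z_j / r}. Positive for like charges (repulsive
#' potential).
#'
#' @param r pair distance in reduced units, strictly positive.
#' @param Zi,Zj integer valences.
#' @param gamma coupling constant \eqn{\Gamma}.
#' @return Potential contribution in reduced units.
#' @export
coulomb_term <- function(r, Zi, Zj, gamma) {
  if (any(r <= 0)) stop("coulomb_term: r must be > 0 (singular at r = 0)")
  gamma * Zi * Zj / r
}

#' Charge-distribution (smearing) term
#'
#' \eqn{t_D(r) = 1 - (1 + r/\lambda)\,e^{-2r/\lambda}}: the correction from
#' replacing point charges with exponentially decaying charge clouds of decay
#' length \eqn{\lambda}. Rises from 0 at contact to 1 at large separation, so
#' the smeared potential is finite everywhere.
#'
#' @param r pair distance, \eqn{r \ge 0}.
#' @param lam decay length \eqn{\lambda > 0}.
#' @return Value in \[0, 1).
#' @export
charge_distribution_term <- function(r, lam) {
  if (!is.numeric(lam) || any(lam <= 0))
    stop("charge_distribution_term: lam must be > 0")
  if (any(r < 0)) stop("charge_distribution_term: r must be >= 0")
  u <- r / lam
  1 - (1 + u) * exp(-2 * u)
}

#' SP3 splitting term
#'
#' Polynomial factor approximating the contribution of periodic mirror
#' charges otherwise requiring an Ewald sum:
#' \deqn{t_S(x) = 1 - \tfrac{7}{4}x + \tfrac{21}{4}x^5 - 7x^6 + \tfrac{5}{2}x^7,
#'   \quad x = r / R_{cutoff,el}.}
#' Both \eqn{t_S} and its derivative vanish at the cutoff, giving a smooth
#' truncation.
#'
#' @param r pair distance in \[0, `cutoff_el`\].
#' @param cutoff_el electrostatic cutoff radius.
#' @return Splitting factor.
#' @export
splitting_term <- function(r, cutoff_el) {
  if (any(r < 0)) stop("splitting_term: r must be >= 0")
  if (any(r > cutoff_el))
    stop("splitting_term: r beyond cutoff_el (interactions past the cutoff never reach this term)")
  x <- r / cutoff_el
  1 - 1.75 * x + x^5 * (5.25 - 7 * x + 2.5 * x^2)
}

# internal: derivative of tD wrt r
d_charge_distribution_term <- function(r, lam) {
  u <- r / lam
  (1 / lam) * (1 + 2 * u) * exp(-2 * u)
}

# internal: derivative of tS wrt r
d_splitting_term <- function(r, cutoff_el) {
  x <- r / cutoff_el
  (1 / cutoff_el) * (-1.75 + x^4 * (26.25 - 42 * x + 17.5 * x^2))
}

#' Electrostatic pair potential for a configured scheme
#'
#' Product of the active factors of \eqn{U_E = t_C t_D t_S}; factors not part
#' of the scheme are set to one. Distances beyond `cutoff_el` give 0. For CD
#' and CDS the contact limit is finite,
#' \eqn{U_E(0) = \Gamma Z_i Z_j / \lambda}, and is returned at very small
#' separations by its analytic value.
#'
#' @param cfg an [elec_config()].
#' @param r pair distance(s), reduced units.
#' @param Zi,Zj integer valences.
#' @return Potential energy in reduced units.
#' @export
electrostatic_potential <- function(cfg, r, Zi, Zj) {
  stopifnot(inherits(cfg, "elec_config"))
  if (cfg$scheme == "none") return(rep(0, length(r)))
  if (any(r < 0)) stop("electrostatic_potential: r must be >= 0")
  if (cfg$scheme == "C" && any(r == 0))
    stop("electrostatic_potential: r = 0 is singular under scheme C")
  vapply(r, function(ri) {
    if (ri >= cfg$cutoff_el) return(0)
    if (cfg$scheme == "C") return(coulomb_term(ri, Zi, Zj, cfg$gamma))
    if (ri < 1e-12) { # analytic contact limit of tC * tD (tS(0) = 1)
      u <- cfg$gamma * Zi * Zj / cfg$lam
    } else {
      u <- coulomb_term(ri, Zi, Zj, cfg$gamma) *
        charge_distribution_term(ri, cfg$lam)
    }
    if (cfg$scheme == "CDS") u <- u * splitting_term(ri, cfg$cutoff_el)
    u
  }, numeric(1))
}

#' Electrostatic pair force for a configured scheme
#'
#' Signed magnitude of \eqn{F^E_{ij} = -\,dU_E/dr} along the unit vector from
#' particle j to particle i; positive values are repulsive. Under scheme C the
#' magnitude is truncated at `cfg$force_cap`, and at r = 0 the cap is returned
#' with the sign of the charge product (documented degenerate case). Under CD
#' the force vanishes at contact; under CDS it tends to
#' \eqn{7\Gamma Z_i Z_j/(4\lambda R_{cutoff,el})}. Beyond `cutoff_el` the
#' force is 0.
#'
#' @inheritParams electrostatic_potential
#' @return Signed force magnitude(s) in reduced units.
#' @export
electrostatic_force <- function(cfg, r, Zi, Zj) {
  stopifnot(inherits(cfg, "elec_config"))
  if (any(r < 0)) stop("electrostatic_force: r must be >= 0")
  if (cfg$scheme == "none") return(rep(0, length(r)))
  code <- scheme_code(cfg)
  vapply(r, function(ri)
    cpp_elec_force_scalar(ri, as.numeric(Zi) * as.numeric(Zj), code,
                          cfg$gamma, cfg$lam, cfg$cutoff_el, cfg$force_cap),
    numeric(1))
}

#' Tabulate the electrostatic force along a distance grid
#'
#' Produces the force-versus-distance table used for scheme comparison plots
#' (unit like charges by default). For CD and CDS the curve rises from a
#' finite contact value through a single interior maximum and decays; for C it
#' is the truncated \eqn{\Gamma/r^2}.
#'
#' @param cfg an [elec_config()].
#' @param r_grid distances within \[0, `cfg$cutoff_el`\].
#' @param Zi,Zj valences (default +1, +1).
#' @param file optional path; when given the table is written as TSV with
#'   header `r<TAB>F`.
#' @return data.frame with columns `r` and `F`.
#' @export
force_curve <- function(cfg, r_grid = seq(0, cfg$cutoff_el, by = 0.01),
                        Zi = 1L, Zj = 1L, file = NULL) {
  if (any(r_grid < 0) || any(r_grid > cfg$cutoff_el))
    stop("force_curve: r_grid must lie within [0, cutoff_el]")
  tab <- data.frame(r = r_grid,
                    F = electrostatic_force(cfg, r_grid, Zi, Zj))
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("r", "F"))
  tab
}
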