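---
title: "Charge treatment in dissipative particle dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge treatment in dissipative particle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdcharge)
```

## The problem

Mesoscopic simulations of biomolecular membranes coarse-grain small
molecules into soft beads: dissipative particle dynamics (DPD) replaces hard
atomistic interactions with soft repulsions, which allows microsecond
timescales for systems representing millions of atoms. Charged species —
phospholipid head groups, ions, charged peptide residues — then pose a
problem: a hard $1/r$ Coulomb interaction is alien to a soft-bead fluid.
Point charges embedded in soft spheres can collapse onto each other, and
even a force-truncated Coulomb interaction tuned to avoid visible pair
sticking can leave behind *statistical* ion pairing: an anomalous excess of
counter-ions at contact that subtly biases quantitative observables, such as
the rate at which membrane-active cyclic peptides extract lipids from a
bilayer.

`dpdcharge` implements and contrasts the three standard charge treatments
in a self-contained DPD simulator:

* **C** — pure Coulomb, $t_C(r) = \Gamma Z_i Z_j / r$, with the force
  magnitude truncated at a cap (default 25 reduced units);
* **CD** — Coulomb multiplied by a charge-distribution term
  $t_D(r) = 1 - (1 + r/\lambda)e^{-2r/\lambda}$, which smears each point
  charge into an exponentially decaying cloud of decay length $\lambda$ and
  makes the pair force finite everywhere (zero at contact);
* **CDS** — CD multiplied by an SP3 splitting term
  $t_S(x) = 1 - \tfrac{7}{4}x + \tfrac{21}{4}x^5 - 7x^6 + \tfrac{5}{2}x^7$,
  $x = r/R_{\mathrm{cutoff,el}}$, a polynomial approximation to the
  contribution of periodic mirror charges otherwise requiring an Ewald sum;
  $t_S$ and its derivative vanish at the cutoff, so the truncation is
  smooth.

The pair potential is the product $U_E = t_C\, t_D\, t_S$ of whichever
terms the scheme activates (inactive terms are one), and the force is its
analytic derivative via the product rule. Useful limits, all covered by
tests: $t_D(0) = 0$, $t_D(\lambda) = 1 - 2e^{-2}$, $t_S(0) = 1$,
$t_S(R_{\mathrm{c,el}}/2) = 51/256$, $F^{CD}(0) = 0$, and
$F^{CDS}(0) = 7\Gamma Z_iZ_j / (4\lambda R_{\mathrm{c,el}})$.

## Reduced units and the coupling constant

The package works in reduced DPD units: the conservative cutoff is the
length unit, $k_BT = 1$ at the target temperature, and bead mass is 1. The
strength of electrostatics in these units is the dimensionless coupling
constant
$$\Gamma = \frac{e^2}{4\pi\epsilon_0 k_B\; \epsilon_r(T)\, R_{\mathrm{cutoff}}\, T},$$
with $R_{\mathrm{cutoff}}$ the physical size of one reduced length unit in
ångström. The numerator is stored as the fixed constant
`COULOMB_PREFACTOR_AA_K` = 167100.946898 Å·K rather than recomputed at run
time, for bit-stable reproducibility; a unit test verifies it against the
CODATA values of $e$, $\epsilon_0$ and $k_B$. The relative permittivity of
water uses a cubic polynomial in $T$ valid between 273 and 373 K. Note a
physical subtlety the tests pin down: because $\epsilon_r$ falls faster
than $1/T$, the product $\epsilon_r T$ *decreases* with temperature, so
$\Gamma$ increases with $T$ — water's Bjerrum length grows as it warms.

```{r}
relative_permittivity(298.15)
coupling_constant(298.15, 4.48)
```

The smearing decay length defaults to $\lambda = \Gamma$ in reduced length
units (the conventional choice for this charge-distribution form), but is
independently settable in `elec_config()` for sensitivity studies.

### Unit mapping

Physical interpretations of reduced lengths and steps are deliberately
configuration values, not constants (`unit_mapping()`). The defaults are
4.48 Å per reduced length unit — the one-water-molecule-per-bead mapping at
number density $\rho = 3$, i.e. $(3 \times 30\,\text{Å}^3)^{1/3}$ — and
50 ps per integration step. Published coarse-grained work quotes slightly
different, mutually inconsistent conversions depending on context (e.g.
4.4 vs 4.9 Å per unit, 50 vs 60 ps per step); the package takes no side and
lets the mapping be set per run. Only derived outputs (extraction rates in
%/µs) depend on it.

## The DPD engine

Forces on each bead sum five pairwise contributions: the conservative soft
repulsion $a_{ij}(1-r)$ for $r < 1$; the dissipative force
$-\gamma w_D(r)(\hat r \cdot v_{ij})\hat r$ with $w_D = (1-r)^2$; the
random force $\sigma w_R(r)\theta_{ij}\hat r/\sqrt{\Delta t}$ with
$w_R = (1-r)$; harmonic bond forces $-k(r - r_0)$; and the electrostatic
force of the configured scheme. The fluctuation–dissipation relation
$\sigma^2 = 2\gamma k_BT$ is enforced at construction, so the
dissipative/random pair acts as a momentum-conserving thermostat.

Since the reference work specifies no standard-DPD parameters, the package
adopts the canonical water-like closure: $\rho = 3$, $a_{ii} = 25$,
$\sigma = 3$ (hence $\gamma = 4.5$), $\Delta t = 0.04$, integrated with the
modified velocity-Verlet scheme at $\lambda = 0.5$ (the dissipative force
is evaluated at the half-step predicted velocity). At $\Delta t = 0.04$
this integrator runs measurably warm — the suite checks the kinetic
temperature stays within 3% of target, and within 1% at $\Delta t = 0.01$;
this is the well-known step-size artifact of the scheme, not a thermostat
defect.

Numerical design choices worth knowing:

* **Pair noise is counter-based.** $\theta_{ij}$ at a given step is a hash
  of (seed, step, unordered pair), uniform on $[-\sqrt3, \sqrt3]$ (zero
  mean, unit variance — only the first two moments matter for the
  thermostat). This makes the random force exactly symmetric in $(i,j)$,
  trajectories bitwise reproducible, and force totals independent of
  traversal order.
* **Two neighbour structures.** The conservative/thermostat loop uses a
  cell list at cutoff 1; electrostatics uses a second list over charged
  beads only at cutoff 5 or 10. Cells are stored as cell-sorted packed
  coordinate arrays with the periodic image shift resolved per
  neighbour-cell offset, so the hot loop does no per-pair minimum-image
  rounding. When a box is too small for three cells per dimension at the
  requested cutoff the code falls back to an all-pairs loop; a brute-force
  path is also exposed (`compute_forces(..., method = "brute")`) and the
  suite requires cell-list and all-pairs totals to agree to $10^{-10}$.
* **Contact limits are analytic.** Below $r = 10^{-6}$ the CD force is 0
  and the CDS force is $7\Gamma Z_iZ_j/(4\lambda R_{\mathrm{c,el}})$,
  evaluated from the limit expressions rather than as a product of
  diverging and vanishing factors — avoiding catastrophic cancellation.
  Exactly coincident beads (the builders' co-located ion pairs at step 0)
  exert no mutual force, since no direction is defined; surrounding beads
  separate them within a few steps.
* **The C-scheme cap applies to forces only.** The C potential remains
  $\Gamma Z_iZ_j/r$ and is not energy-consistent with the capped force;
  DPD dynamics consumes forces only, and capping energies would change the
  model. The C force also stops discontinuously at the electrostatic
  cutoff; the smeared schemes either decay strongly (CD) or vanish
  smoothly by construction (CDS).
* **No bonded exclusions for electrostatics.** Charges interact across all
  pairs including bonded neighbours; fragment-based coarse-graining places
  charges on distinct beads, and the model defines no exclusion rule.
* **Walls.** Non-periodic dimensions (the sandwich z-axis) combine a soft
  repulsive wall of the conservative form within 1 reduced unit of each
  face with a reflecting boundary; no particle can leave the box. Walls
  exchange momentum with the system, so momentum conservation is asserted
  only along periodic dimensions.

## The two experiment builders

Both builders are pure functions of their spec plus a seed, and both draw
Maxwell velocities at $k_BT = 1$ with zero total momentum. Random
placements are rejected below 0.01 reduced units of separation to avoid
initial force spikes.

**Ion-pair water box** (`build_ion_water_box()`): a fully periodic box of
water beads containing $n$ monovalent ion pairs (and optionally uncharged
control pairs), each pair initially co-located at one point. Pair
separation over time is the classic tuning diagnostic for the truncated
Coulomb scheme: the coupling is considered tuned when charged pairs
separate like uncharged ones. The default experiment
(`ion_pairing_experiment()`) uses a $10^3$ box at $\rho = 3$ — 3,000 beads
with 100 ion pairs, a 150-fold linear scale-down of the corresponding
2-million-particle production system — with 2,000 equilibration and 20,000
production steps.

**Membrane/peptide sandwich** (`build_sandwich()`): two preassembled
bilayers normal to z near the faces of a box periodic in x,y only, outer
leaflets facing a central water compartment holding peptide surrogates and
counter-ions. The toy lipid is a head bead (charged per class) bonded to a
4-bead tail ($k = 100$, $r_0 = 0.7$); the hydrophobic contrast lives in
the repulsion matrix (water–tail 80, head–tail 50, baseline 25). The
plasma-membrane composition preset reproduces the cholesterol-free
five-lipid mixture (40% DMPC, 20% DOPE, 5% PIP2, 10% DOPS, 25% SM) with
its strongly asymmetric leaflet splits (DMPC 24:76 inner:outer, DOPE
77.5:22.5, PIP2 75:25, DOPS inner-only, SM 22:78) by largest-remainder
rounding; head valences are toy surrogates (−1 DOPS, −4 PIP2, 0
otherwise). The peptide surrogate is a closed ring of 12 backbone beads —
the cyclic topology of a cyclotide — carrying a hydrophobic patch (beads
with reduced repulsion, 15, against lipid tails) and optional charged side
beads for the 0 vs +3 net-charge contrast. Real cyclotide fragment
parametrizations are deliberately out of scope; the surrogate preserves
the mechanistic degrees of freedom (ring, patch, charge state) that the
scheme comparison varies. Bilayers are preassembled rather than
self-assembled to keep runs at desk scale, and the area per lipid defaults
to 1.2 reduced units² — a toy value chosen for bilayer stability, not a
measured one.

## Analyses

**RDFs.** `radial_distribution()` histograms minimum-image pair distances
(default bin 0.05, range 4) and normalizes by the ideal-gas shell
expectation at the observed partial densities; a pure-R oracle pins the
histogram exactly in tests. For a charge-symmetric electrolyte the RDFs
should satisfy the product law
$g_{+-}(r)\,g_{--}(r) = g^2(r)$ with $g$ the uncharged reference;
`rdf_product_check()` reports the per-bin residual and its maximum over
bins with at least 500 raw counts. Violation at contact — a large unlike
peak not compensated by like-pair depletion — is the statistical
ion-pairing fingerprint of the truncated Coulomb scheme.

**Extraction rate.** `lipid_extraction_trace()` counts an outer-leaflet
lipid as extracted when its centre of geometry sits more than 3 reduced
units from its source bilayer's midplane toward the compartment for at
least 2 consecutive emitted frames, and fits a least-squares line to the
percentage over an intermediate window — by default the middle
[10%, 60%] of the trajectory, reported alongside the rate, since membrane
disruption is linear only between its onset and saturation. Threshold,
persistence and window are explicit parameters (the reference procedure
for them is not public); the estimator itself is validated against
constructed trajectories with known rates to 1%.

## What the scaled-down experiments do and do not show

The default problem sizes (3,000-bead ion boxes over 22,000 steps;
~4,600-bead sandwiches) were chosen so the full suite runs on one CPU in
minutes. At this scale the package reproduces the qualitative and
semi-quantitative structure of the full-size study: the truncated-Coulomb
scheme, even tuned so initially co-located pairs separate like uncharged
ones ($\Gamma_C = 1$), shows a pronounced contact peak in $g_{+-}$ that
the smeared schemes lack; the smeared schemes satisfy the product law
within statistical tolerance; CDS converges to CD as the electrostatic
cutoff grows. What the desk scale does *not* probe: 2-million-particle
hydrodynamics, microsecond-scale peptide oligomerization and tubular
superstructure formation, and production-grade extraction-rate
statistics — the toy sandwich demonstrates the machinery (builder, run,
estimator), not membrane-biology conclusions. Likewise the synthetic
systems contain no real lipid force-field detail: conclusions about real
membranes require the fragment parametrizations excluded here.

## Known limitations

* No Ewald sum, reaction field or polarizable electrostatics: CDS's
  polynomial splitting is the only mirror-charge approximation.
* No barostat, constraints or rigid bodies; NVT only.
* The C scheme's capped force is not energy-consistent with its potential
  (inherent to force truncation).
* Single-threaded; determinism is guaranteed by construction rather than
  by ordering contracts across threads.
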