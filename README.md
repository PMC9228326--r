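# dpdcharge

Dissipative particle dynamics (DPD) with explicit charge treatment, built
to study how the handling of electrostatics changes what mesoscopic
membrane simulations measure. DPD coarse-grains small molecules into soft
beads — ideal for microsecond membrane processes such as peptide-induced
lipid extraction — but a hard Coulomb interaction between charged beads is
foreign to a soft fluid and creates artifacts. This package implements the
three standard charge schemes side by side, in one engine, with the two
experiment types that discriminate them.

## The schemes

The electrostatic pair potential factorizes as a product
$U_E(r) = t_C(r)\, t_D(r)\, t_S(r)$:

| scheme | terms | behaviour at contact |
|---|---|---|
| **C** | $t_C = \Gamma Z_i Z_j / r$, force truncated at 25 | capped $1/r^2$ force |
| **CD** | $t_C \cdot t_D$, $t_D = 1-(1+r/\lambda)e^{-2r/\lambda}$ | force → 0 |
| **CDS** | $t_C \cdot t_D \cdot t_S$ (SP3 splitting polynomial) | force → $\frac{7\Gamma Z_iZ_j}{4\lambda R_{c,el}}$ |

with the dimensionless coupling constant
$\Gamma = e^2 / (4\pi\epsilon_0 k_B\, \epsilon_r(T)\, R_{\mathrm{cutoff}}\, T)$,
the smearing decay length $\lambda = \Gamma$ by default, and an
electrostatic cutoff of 5 or 10 reduced length units. $t_S$ approximates
the periodic mirror charges an Ewald sum would handle; it and its
derivative vanish smoothly at the cutoff.

The discriminating observation: a truncated Coulomb scheme tuned so that
initially co-located ion pairs separate like uncharged pairs still
produces *statistical* ion pairing — an anomalous contact peak in the
unlike-ion radial distribution function $g_{+-}(r)$ that violates the
electrolyte product law $g_{+-}\, g_{--} = g^2$. Charge smearing removes
it. The package reproduces this contrast at desk scale, plus the
machinery for membrane-disruption rates (percent of outer-leaflet lipids
extracted per microsecond) in a two-membrane "sandwich" system.

## Worked example

```r
library(dpdcharge)

## coupling constant for one water bead per particle (4.48 A per reduced
## length unit) at 298.15 K
gam <- coupling_constant(298.15, 4.48)
gam
#> [1] 1.597666

## forces between unit like charges at r = 0.5 under the three schemes
## (the CDS contact repulsion exceeds CD's because of the splitting-term
## derivative; CD vanishes smoothly toward contact)
cfgC   <- elec_config("C",   gamma = 1,   cutoff_el = 5)  # tuned Coulomb
cfgCD  <- elec_config("CD",  gamma = gam, cutoff_el = 5)
cfgCDS <- elec_config("CDS", gamma = gam, cutoff_el = 5)
sapply(list(C = cfgC, CD = cfgCD, CDS = cfgCDS),
       electrostatic_force, r = 0.5, Zi = 1, Zj = 1)
#>         C        CD       CDS 
#> 4.0000000 0.1645755 0.4684830

## scaled-down ion-pairing experiment: 3,000 beads, 100 ion pairs,
## 20,000 production steps (about 2 min each on one CPU)
ex_cd <- ion_pairing_experiment("CD", seed = 1)
ex_c  <- ion_pairing_experiment("C",  seed = 1)

## smeared charges obey the electrolyte product law ...
ex_cd$product$max_residual
#> [1] 0.04895127

## ... while truncated Coulomb shows a statistical pairing peak at contact
## that CD lacks at the same distance
ex_c$peak
#> $r
#> [1] 0.025
#> $g
#> [1] 5.252113
ex_cd$g_unlike_at(ex_c$peak$r)
#> [1] 0
```

`ex_c$peak$g` is the height of the maximum of $g_{+-}$ under the pure
Coulomb scheme — a five-fold excess of counter-ions at contact relative to
an ideal solution, even though the coupling was tuned to make tracked pair
separations match uncharged controls. Under CD the same distance shows a
depleted $g_{+-} \approx 0$: enrichment appears only as smooth coordination
shells, and the product-law residual stays at the few-percent level of
statistical noise.

The sandwich workflow runs through the same engine:

```r
sys <- build_sandwich(sandwich_spec(n_peptides = 4, peptide_charge = 0,
                                    seed = 1))
res <- run_simulation(sys$state, 10000, sys$params, sys$topo,
                      elec_config("CDS", gamma = gam), emit_every = 500)
lipid_extraction_trace(res$frames, sys$membranes, unit_mapping(),
                       emit_every = 500)
```

A command-line front end (`inst/scripts/dpdcharge`) wraps the same
functions as `build` / `run` / `analyze` / `curves` subcommands over YAML
run configurations.

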