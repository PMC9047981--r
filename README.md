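# smdcycle

Absolute protein–protein binding free energies from steered simulations
over a restrained thermodynamic cycle — with the Jarzynski
nonequilibrium work estimator, standard-state and
rotational-restriction corrections, and structural interface analysis.

## What it does, and for whom

Computing the absolute binding free energy of a flexible dimer directly
is hopeless; the confinement strategy replaces the real binding process
with three *virtual* processes between strongly restrained states, each
cheap to steer:

* **A** — release all restraints in the unbound state,
* **B** — pull the restrained monomers together along a fixed axis,
* **C** — release all restraints in the bound state,

assembled as

```
ΔF = −ΔF_A + ΔF_B + ΔF_C + ΔF_V + ΔF_R,     σ = sqrt(s_A² + s_B² + s_C²)
```

where ΔF_V = k_BT ln(V₀/V_u) references the restrained unbound volume
V_u to the standard-state volume V₀ = 1661 Å³ and
ΔF_R = k_BT ln(Δr_y,b Δr_z,b / 4πr_b²) accounts for the orientational
freedom suppressed by the bound-state restraints. Each process free
energy comes from the Jarzynski equality,
`exp(−βΔF) = ⟨exp(−βW)⟩`, over an ensemble of steered trajectories.

The package is for computational structural biologists and method
developers: it provides a restrained-toy Langevin engine with the full
eleven-restraint vocabulary (CV spring, structure, planar, point and
flat-bottom restraints), work-trace estimation with bootstrap errors,
cycle assembly, exact quadrature oracles for validation, and interface
analyzers (Shrake–Rupley SASA and ΔSASA ranking, π–π and hydrogen-bond
detection with per-frame occupancy, alanine-truncation mutants, the
0.0072 × SASA nonpolar solvation model).

## Worked example

Assemble a cycle from measured process free energies and corrections:

```r
library(smdcycle)
comp <- cycle_components(dF_A = -77.88, dF_B = -25.02, dF_C = -61.66,
                         s_A = 0.89, s_B = 0.95, s_C = 0.53,
                         dF_V = 5.45, dF_R = -5.62)
assemble_cycle(comp)
#> Thermodynamic-cycle binding free energy
#>   dF_A (unbound release) =   -77.88 +/- 0.89 kcal/mol
#>   dF_B (virtual binding) =   -25.02 +/- 0.95 kcal/mol
#>   dF_C (bound release)   =   -61.66 +/- 0.53 kcal/mol
#>   dF_V (standard state)  =     5.45 kcal/mol
#>   dF_R (rotational)      =    -5.62 kcal/mol
#>   dF = -dF_A + dF_B + dF_C + dF_V + dF_R = -8.97 +/- 1.41 kcal/mol
#>   (steering along a fixed axis: no Jacobian correction required)
```

The assembled −8.97 ± 1.41 kcal/mol is the absolute binding free
energy referenced to the 1 mol/L standard state; the ± is the
quadrature of the three simulated-process errors (corrections are
treated as exact).

Steer a toy dimer yourself and estimate its binding profile:

```r
toy <- make_toy_dimer(toy_dimer_spec(beads = 1))   # 11 restraints, k = 50
sch <- smd_schedule("center", lambda0 = 9, v = -0.2, duration = 30)
out <- run_smd(toy$system, toy$restraints, sch, dt = 0.002, seed = 1,
               n_traj = 20, n_equil = 2500)
prof <- build_profile(out$traces, 298, n_boot = 300, seed = 1)
profile_minimum(prof)
#> profile minimum: dF = -2.94 +/- 0.06 kcal/mol at 3.4 A
```

The minimum sits at 3.4 Å — one grid point inside the pull range,
next to the Lennard-Jones minimum at 2^(1/6)·3 ≈ 3.37 Å — and its
depth approaches the interface well depth (ε = 3 kcal/mol) plus
restrained-fluctuation contributions; the quadrature oracle
`pmf_oracle_1d()` gives the exact reference curve.

Interface analysis on a structure:

```r
s <- read_pdb("dimer.pdb")
sasa(s)$total                          # Shrake-Rupley, Bondi radii
detect_pipi(s, monomers = list(I = c("A","B"), II = c("C","D")))
detect_hbonds(s, monomers = list(I = c("A","B"), II = c("C","D")))
mutate_to_ala(s, "B", 24)              # backbone + CB, renamed ALA
```

A thin command line (`inst/cli/smdcycle.R`) exposes the same pipeline
as subcommands (`pull`, `release`, `estimate`, `cycle`, `analyze`,
`mutate`, `fixtures`, `simulate`), writing work traces as TSV,
trajectories as multi-model PDB and a reproducibility manifest per run.

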