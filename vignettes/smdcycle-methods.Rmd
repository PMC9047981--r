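---
title: "Methods: restrained-cycle binding free energies with smdcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restrained-cycle binding free energies with smdcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdcycle)
```

## The problem and the model

Computing the absolute binding free energy of a flexible protein–protein
dimer head-on is intractable: the unbound monomers explore a huge
configurational volume and the binding path is slow. The confinement
strategy implemented here circumvents this with a fictitious
thermodynamic cycle. The real binding process (flexible unbound monomers
→ flexible complex) is replaced by three virtual processes between
*restrained* states:

* **Process A** — in the unbound state, release all geometric restraints
  (restrained → flexible).
* **Process B** — with all restraints held at full strength, pull the
  two monomers together along a fixed axis (virtual binding).
* **Process C** — in the bound state, release all restraints.

Because the cycle closes,

$$\Delta F = -\Delta F_A + \Delta F_B + \Delta F_C + \Delta F_V + \Delta F_R,$$

where $\Delta F_V$ and $\Delta F_R$ are the standard-state and
rotational-restriction corrections described below. Each virtual process
is simulated by steered dynamics: a restraint parameter $\lambda$ is
driven linearly in time, $\lambda = \lambda_0 + vt$, and the external
work $W$ of many independent trajectories is combined with the Jarzynski
equality

$$\exp(-\beta \Delta F) = \langle \exp(-\beta W) \rangle ,$$

which holds at any driving speed; slower driving only reduces the
statistical burden. For centre steering the spring potential is
$V = \tfrac{1}{2}k\,(\xi(\mathbf r)-\lambda)^2$ with the collective
variable $\xi$ the mass-weighted monomer–monomer centre-of-mass distance
along the X axis. For the release processes the driven coordinate is the
shared force constant $k$ itself. Steering along a fixed axis means no
Jacobian correction is needed.

## The restraint vocabulary

Eleven restraints define the restrained states
(`make_toy_dimer()` emits all of them):

1. the CV spring on the COM X-distance;
2. –3. one structure restraint per monomer: a harmonic penalty
  $\tfrac{1}{2}k\,\mathrm{MSD}$ on the mean-square deviation of
  *centroid-centred* coordinates from the centred reference. Removing
  the centroid (no rotational fit) keeps this a pure internal-structure
  restraint that cannot fight the CV pulling; rotation is already pinned
  by the point restraints, so a rotational superposition is
  deliberately omitted;
4. –5. one planar restraint per monomer,
  $\tfrac{1}{2}k(\Delta y^2 + \Delta z^2)$ on the monomer COM, keeping
  the binding direction on the X axis;
6. –11. six single-bead point restraints — per monomer one axis fix
  (y and z), one X–Y-plane fix (z) and one X–Z-plane fix (y) — removing
  rigid-body rotation.

A flat-bottom umbrella on the 3-D COM separation is available for
fixed-distance sampling: zero on $[r_2, r_3]$, harmonic on
$[r_1, r_2]$ and $[r_3, r_4]$, and linear with matched slope beyond the
outer knots (the knots alone do not determine the outer branches; the
matched-slope linear continuation is the common MD-restraint dialect).

## Corrections

The restrained unbound state confines the monomer–monomer separation to
a volume $V_u = \Delta r_{x,u}\,\Delta r_{y,u}\,\Delta r_{z,u}$
measured as min-to-max spans of the separation components. Referencing
to the standard-state volume $V_0 = 1661\ \mathrm{\AA}^3$ (1 mol/L):

$$\Delta F_V = k_B T \ln\!\frac{V_0}{V_u},$$

positive whenever $V_u < V_0$. The bound-state restraints also suppress
the relative orientational freedom the flexible complex would have: the
restrained pair explores a transverse patch
$\Delta r_{y,b}\,\Delta r_{z,b}$ of the sphere of radius $r_b$ (the mean
radial separation of the unrestrained complex):

$$\Delta F_R = k_B T \ln\!\frac{\Delta r_{y,b}\,\Delta r_{z,b}}{4\pi r_b^2},$$

negative for tight restraints. `measure_correction_inputs()` takes the
spans from a restrained unbound run, the maximum absolute deviations
about the mean from a restrained bound run, and $r_b$ from an
unrestrained bound run (the restrained bound frames stand in when no
unrestrained run is supplied). Both corrections use range statistics,
so their values depend (logarithmically weakly) on sampling length;
they are treated as errorless in the propagated uncertainty
$\sigma = \sqrt{s_A^2 + s_B^2 + s_C^2}$, which is how the three-process
quadrature reproduces a published ±1.41 from ±0.89/±0.95/±0.53.

## Dynamics, work accounting and randomness

The engine integrates Langevin dynamics with the BAOAB splitting
(friction default 5 ps⁻¹); with zero friction and temperature it reduces
to velocity Verlet, which the tests use for energy-conservation checks.
Units are kcal/mol, Å, ps, amu, K with
$k_B = 0.0019872$ kcal mol⁻¹ K⁻¹.

Work uses the discrete-protocol convention: each step the driven
parameter jumps at fixed coordinates and
$W \mathrel{+}= V(\mathbf x;\lambda_{new}) - V(\mathbf x;\lambda_{old})$,
then the system propagates at the new parameter. To first order in the
time step this equals $-k(\xi-\lambda)\,v\,\mathrm dt$ for centre
steering and $\tfrac{1}{2}(\xi-\lambda)^2\,\mathrm dk$ summed over the
ramped restraints for force-constant steering, and it makes the
Jarzynski identity exact for the discrete chain rather than only to
$O(\mathrm dt)$.

Every trajectory derives its own noise stream from the master seed and
its trajectory index (in fixed-size chunks), so trajectory $i$ is
reproducible on its own; the ensemble is propagated vectorized, so
work values agree across ensemble sizes up to floating-point
associativity. Work is recorded on a uniform grid of the driven
quantity (default 0.1 Å, or 0.5 kcal mol⁻¹ Å⁻² for force-constant
ramps).

Estimation uses a max-shifted log-mean-exp (naive exponentials overflow
near $\beta W \approx 700$); profile errors are pointwise bootstrap
standard deviations over whole-trajectory resamples (default 1000
resamples), reported as 1 SD. The exponential estimator is biased low
for small ensembles with broad work distributions; the convergence
tests below quantify this directly.

## The synthetic toy and what it does (not) show

The toy dimer stands in for the real system: beads per monomer
(default 3), harmonic intra-monomer bonds, and a Lennard-Jones
interface (defaults $\varepsilon = 3$ kcal/mol, $\sigma = 3$ Å,
298 K). By default the interface potential acts on the *collective
variable itself* (the COM X-distance). This "axial" choice is what
makes the toy's thermodynamics exactly reducible to one-dimensional
quadrature: the transverse degrees of freedom are then harmonic at
every stage and cancel identically between the two release processes,
so `exact_free_energy_1d()` is a true oracle for the assembled cycle.
A bead-pair 3-D Lennard-Jones mode is available but couples the
transverse restrained coordinates to the CV and has no exact 1-D
reference.

Releases go to a force-constant floor $k_{floor} = 0.5$ rather than 0:
a completely free particle has no normalizable reference state, so
"flexible" toy states keep a weak confinement and the oracle includes
the same residual CV spring. The closure identity is therefore tested
in this common weak-restraint frame. The volume and orientation
corrections are computed from the same runs and checked for sign and
magnitude
(restrained toy volumes are far below 1661 Å³, hence $\Delta F_V > 0$;
tight transverse restraints give $\Delta F_R < 0$); they are not added
to one side of an otherwise exact identity, because their range-based
estimators would inject sampling-length dependence into the closure.

Study conditions for the cycle validation, fixed once: one bead per
monomer, unbound separation 9 Å, pulling past the interface minimum
($2^{1/6}\sigma \approx 3.37$ Å) to 3.0 Å so the profile minimum is
interior (the bound point of the cycle is taken at the profile minimum,
not the schedule endpoint), $k = 50$ kcal mol⁻¹ Å⁻², 40 trajectories
per process, time step 0.002 ps, slow pulling speed 0.02 Å/ps with
10× and 100× tiers, 50 ps slow release ramps, 10 ps equilibration
before each process. With these sizes the three-tier validation runs
in minutes on one core.

Two convergence facts, measured by the test suite: the process-B
profile's maximum deviation from the quadrature PMF decreases
monotonically through the speed tiers (≈0.63 → 0.10 → 0.03 kcal/mol),
while the *assembled cycle* converges much faster than any single
process because the dissipation biases of the two release processes
enter with opposite signs and largely cancel — the cycle sum is not a
monotone function of speed, and the monotone convergence check
therefore lives on the profile deviation. Passing these tests shows
the estimators and work bookkeeping are correct at toy scale; it does
not show that an explicit-solvent protein system is converged at any
given speed, which remains a per-system judgement.

## Structural analyzers

* **SASA** (`sasa()`): Shrake–Rupley sphere sampling with golden-spiral
  quadrature points (default 960, ≤2 % error on two-sphere analytic
  cases), probe 1.4 Å, Bondi van der Waals radii (`vdw_radii()`);
  unknown elements are an explicit error. `delta_sasa()` ranks
  unbound − bound per-residue differences, ties by residue number.
  The nonpolar solvation model is linear: 0.0072 × SASA.
* **π–π** (`detect_pipi()`): six-membered Phe/Tyr rings; ring normal
  from the smallest singular vector of the centred ring coordinates
  (robust to slight non-planarity); fires for inter-monomer ring-centre
  distance < 7.2 Å with normal–normal acute angle < 30° (parallel) or
  > 50° (T-shaped). All thresholds are strict inequalities; the 30–50°
  band and boundary values do not fire.
* **Hydrogen bonds** (`detect_hbonds()`): inter-monomer donor-N /
  acceptor-O pairs with O–N < 3.0 Å and donor–H–acceptor angle > 135°.
  File hydrogens within 1.25 Å of the donor are used; a backbone N
  without hydrogens gets an ideal amide H along the negative bisector
  of N→CA and N→C(prev) (placements are counted in an attribute);
  donors with no resolvable hydrogen are skipped with a warning.
* **Alanine truncation** (`mutate_to_ala()`): keeps backbone (+ backbone
  hydrogens) plus Cβ, renames the residue ALA, errors on glycine, and
  is idempotent; all other residues are bit-identical.

Residue numbering follows the PDB file as-is; interface notation like
"B24" maps to (chain B, residue 24) via the `monomers` chain-grouping
argument of the detectors.

## Numerical choices and degenerate inputs

* Quadrature oracles use trapezoidal integration with interval halving
  and Richardson extrapolation; the reported `error` is the
  extrapolation estimate and non-convergence is an explicit error.
* `profile_minimum()` breaks ties toward the schedule end.
* Restraint forces are exact analytic gradients (validated to 1e-6
  relative by central differences in the tests); the flat-bottom
  umbrella is $C^1$ at all four knots.
* Bootstrap errors are `Inf` with a warning for fewer than two works;
  single-frame correction measurements are a degenerate-span error;
  one-bead monomers are accepted (their structure restraint is
  identically zero).

## Known limitations

* The toys contain no solvent, no electrostatics by default, and no
  conformational change; nothing here re-creates explicit-solvent
  protein trajectories.
* The exponential work average is biased for small ensembles; error
  bars are bootstrap SDs and inherit that bias.
* The correction terms use range statistics and grow slowly with
  sampling length; for quantitative use, report the sampling protocol
  alongside them.
* SASA absolute values depend on the radii set and point count;
  published per-residue tables are comparable only under matching
  conventions.
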