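---
title: "Spin-Hamiltonian analysis of exchange-coupled Fe–Mn dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-Hamiltonian analysis of exchange-coupled Fe-Mn dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerspec)
```

## The physical problem

Oxo- and hydroxo-bridged Fe(III)–Mn(III/IV) cores — synthetic analogues of
the FeMn cofactors of class Ic ribonucleotide reductase and R2lox — are
characterized magnetically by three interlocking experiments:

* **cw-EPR** of the coupled ground manifold, which for an
  antiferromagnetically coupled S_Fe = 5/2 / S_Mn = 2 pair is an
  S = 1/2 doublet showing a six-line ⁵⁵Mn (I = 5/2) hyperfine pattern
  near g = 2;
* **temperature-dependent EPR and microwave power saturation**, which
  read out the Heisenberg exchange constant J through the Boltzmann
  population of the excited total-spin multiplets and through Orbach
  relaxation across the first ladder gap;
* **variable-field ⁵⁷Fe Mössbauer spectroscopy**, which probes the
  iron-site spin expectation ⟨S_Fe⟩ through the internal field at the
  ⁵⁷Fe nucleus.

`dimerspec` implements all three stages plus the algebra that connects
them: spin-projection mapping between the coupled and site
representations, and — the scientifically distinctive part — a Mössbauer
simulation in which the ⁵⁵Mn nuclear spin is diagonalized *together with*
the electronic system, so that at permanent-magnet fields the manganese
nucleus visibly perturbs what the iron nucleus reports.

## The spin Hamiltonian

All energies are carried in cm⁻¹, fields in tesla, hyperfine couplings in
MHz (converted on demand; see `unit_table()`). The dimer Hamiltonian
assembled by `build_hamiltonian()` is

$$H = J\,\mathbf{S}_1\!\cdot\!\mathbf{S}_2
  + \sum_i \left[ \mathbf{S}_i \mathbf{D}_i \mathbf{S}_i
  + \mu_B \mathbf{B}\,\mathbf{g}_i\,\mathbf{S}_i \right]
  + \sum_n \left[ \mathbf{S}\,\mathbf{A}_n\,\mathbf{I}_n
  - g_n \mu_N \mathbf{B}\!\cdot\!\mathbf{I}_n \right]$$

with the convention **+J S₁·S₂, J > 0 antiferromagnetic**, so positive J
puts the minimal total spin lowest. Exchange-only eigenvalues follow the
closed-form ladder $E(S) = (J/2)[S(S+1) - S_1(S_1+1) - S_2(S_2+1)]$
(`exchange_ladder()`), which the test-suite checks against numerical
diagonalization to 10⁻⁹ for all site spins up to 5/2.

Tensor orientations use **ZYZ Euler angles, in degrees** at every
interface: `euler_matrix(c(alpha, beta, gamma))` returns
$R_z(\alpha)R_y(\beta)R_z(\gamma)$, and a tensor with principal values *p*
rotated by those angles appears in the reference frame as $R\,
\mathrm{diag}(p)\,R^T$. Each site's zero-field-splitting tensor shares
the principal frame of its g-tensor; each nuclear hyperfine tensor is
rotated by its own angles *relative to the site frame*, matching the way
multifrequency EPR fits report "g ∠ A" rotations. The nuclear Zeeman
term is retained although it is negligible at the fields of interest —
it costs nothing and keeps the level diagram honest.

ZFS parameters D and E are accepted on any site (with the canonical
restriction |E/D| ≤ 1/3) but default to zero: for these dimers the site
ZFS (~0.5 cm⁻¹ for the Fe site, ~2 cm⁻¹ for Mn(III)) is small against
J ≳ 40–120 cm⁻¹ and perturbs projected tensors by only a few percent, so
no shipped analysis depends on it.

## Coupled ↔ site projection

For a total-spin-S multiplet of a pair (S₁, S₂) the projection
coefficients are

$$c_i = \frac{S(S+1) + S_i(S_i+1) - S_j(S_j+1)}{2S(S+1)}, \qquad
c_1 + c_2 = 1 .$$

For the S = 1/2 ground doublet of 5/2 ⊗ 2 these are (7/3, −4/3), giving
the familiar results g_c = 2 − (4/3)(g_Mn − 2) (for g_Fe = 2) and
**A_Mn = −(3/4) A^C_Mn** for mapping the fitted coupled ⁵⁵Mn tensor back
to the Mn site. EPR determines only magnitudes, so
`site_A_from_coupled()` resolves signs with an explicit convention —
`"negative_iso"` by default, because the Fermi-contact term of Mn(III)
is negative — and splits the site tensor into its isotropic part
(trace/3) and traceless spin-dipolar remainder:

```{r projection}
proj <- site_A_from_coupled(c(215, 243, 341), c_site = -4/3)
proj
```

Report output rounds A_iso and A_SD to integer MHz, which is the
precision at which such tables are normally printed; comparisons against
published spin-dipolar components should allow ±1.5 MHz because printed
values are typically rounded from the fitted (not the re-derived)
numbers.

## Powder EPR simulation

`simulate_powder_epr()` treats the coupled doublet as an effective
S = 1/2 with one I = 5/2 nucleus. For a field direction **n** in the g
frame the electronic resonance obeys $h\nu = g(n)\mu_B B_0$ with
$g(n)^2 = n^T g^2 n$, and the 2I+1 hyperfine lines are placed by
first-order perturbation theory with splitting
$a(n) = |A\,G\,n|/g(n)$ — adequate because A (≲ 350 MHz) is far below
the microwave quantum (≳ 3.5 GHz). An orientation-dependent Gaussian
FWHM interpolates three principal-axis widths (default 3 mT; the
linewidth is a fit parameter, not a claim about any instrument).

Powder averaging uses a deterministic igloo grid over one octant
(interaction tensors are centrosymmetric), 400 orientations by default;
doubling the grid changes the default-resolution spectrum by well under
1% RMS. Temperature (default 20 K) enters through the thermal
polarization of the doublet. Because the simulation is fast, the
two-frequency simultaneous fit (`fit_epr_multifrequency()`) can afford
seeded multi-start optimization — the Euler angles generate genuinely
distinct local minima, and axis relabelling means recovered tensors are
unique only up to principal-axis permutation.

`effective_g()` serves the half-integer ZFS systems seen at higher
temperature: it diagonalizes $D[S_z^2 - S(S+1)/3] + E(S_x^2 - S_y^2)$
and reads each Kramers doublet as a pseudo-spin 1/2, the construction
behind rhombograms. D > 0 is assumed when naming the "lower" doublet;
for S = 3/2 that is the mostly ±1/2 pair. At E/D = 0.16 the observable
features computed this way are:

```{r effg}
effective_g(3/2, 0.16)
```

## Exchange thermodynamics

`signal_t_product()` models intensity × T of one multiplet as its
degeneracy-weighted Boltzmann fraction over the full ladder; an excited
multiplet rises monotonically towards (2S+1)/(2S₁+1)(2S₂+1).
`fit_exchange_tempdep()` fits J and a scale (optionally a baseline,
default off because a floated baseline is rarely identifiable from
8-point series) and is exactly scale-invariant.

`fit_orbach()` adopts the standard direct-plus-Orbach form

$$P_{1/2}(T) = aT + \frac{b}{e^{\Delta/k_BT} - 1},$$

fitted on the log scale since half-saturation powers span decades. Only
the gap Δ is physically compared across methods; it maps to J through
the first ladder gap, Δ = J(S_min + 1) — i.e. 3J/2 for 5/2 ⊗ 2. The
prefactors a and b are instrument-dependent and are reported but not
interpreted.

## Variable-field Mössbauer simulation

The simulation is built around a deliberate asymmetry:

* the **⁵⁷Fe nucleus is a per-level sub-problem**. Its hyperfine energy
  (~0.001 cm⁻¹) cannot act back on the electronic system, so each
  populated electronic level contributes an 8-line pattern computed in
  the effective field
  $\mathbf{B}_\mathrm{eff} = \mathbf{B}_\mathrm{app} -
  \langle\mathbf{S}_\mathrm{Fe}\rangle\cdot\mathbf{A}_\mathrm{Fe}$,
  with A_Fe quoted in tesla (the energy tensor divided by
  $g_n^\mathrm{gnd}\mu_N$, the standard field-unit convention);
* the **⁵⁵Mn nucleus lives inside the diagonalized space** when
  `include_mn = TRUE`. Its coupling (A_iso ≈ 260 MHz = 0.0087 cm⁻¹) is
  more than 10% of the electronic Zeeman splitting at 45 mT
  (≈ 0.04 cm⁻¹), so at permanent-magnet fields the electron–nuclear
  eigenstates carry mixed character and the distribution of ⟨S_Fe⟩
  across the populated levels broadens, shrinking the apparent magnetic
  splitting. At tesla-scale fields the electronic Zeeman term dominates
  and the Mn nucleus becomes irrelevant — the package reproduces both
  regimes, and the test suite pins the crossover (simulations with and
  without the Mn term differ by >5% RMS at 7.5 and 45 mT and by <1% at
  4 T).

Per orientation and populated level, the I = 1/2 ground and I = 3/2
excited nuclear Hamiltonians (excited-state quadrupole interaction with
splitting ΔE_Q and asymmetry η, EFG frame tied to the A_Fe frame) are
diagonalized in a frame quantized along **B**_eff; M1 transition
amplitudes use Clebsch–Gordan coefficients, with ΔM = 0, ±1 components
weighted by the beam geometry. The azimuth of the molecule about the
applied field is averaged analytically, which drops q-interference
terms — exact for the powder averages computed here. Applied field
**perpendicular** to the γ-beam is the default (the common
permanent-magnet arrangement); `"parallel"` is available. The correct
limiting intensity ratios (3:2:1:1:2:3 for randomly oriented internal
fields, 3:4:1 transverse, 3:0:1 parallel) all emerge from this one
angular treatment.

Assumptions: slow-relaxation (static) limit, appropriate at 4.2 K;
thin-absorber (intensities add linearly, total absorption area is
conserved across fields); η defaults to 0 since the EFG asymmetry of
these near-axial sites is not independently determined. Mixtures are
fraction-weighted sums.

`fit_mossbauer()` fits (δ, ΔE_Q, isotropic A_Fe, optionally Γ and a
minor-species fraction) simultaneously over all fields. The ⁵⁵Mn tensor
is *never* floated there — it is fixed at the EPR-derived value, which
is the whole point of the combined analysis. Because none of the
floated parameters enter the electronic Hamiltonian, the electronic
diagonalization is done once per field/orientation and each optimizer
iteration redoes only the cheap nuclear stage; per-spectrum amplitudes
are profiled out analytically. For identifiability, include at least
one field ≤ 50 mT and one ≥ 1 T; with zero-field data alone the sign of
ΔE_Q is fundamentally undetermined and the fit says so.

A projected alternative (`electronic = "doublet"`) replaces the full
30-dimensional (or 180 with Mn) dimer space by the ground multiplet
with projected g and A tensors. In the strong-exchange regime
(J ≥ 100 cm⁻¹ at 4.2 K) it matches the full treatment to better than 2%
RMS and is the natural choice inside long fits.

## The synthetic-data generator

Every experiment the package can fit it can also generate
(`generate_epr_dataset()`, `generate_tempdep_dataset()`,
`generate_psat_dataset()`, `generate_mossbauer_dataset()`), from
declared truth, with additive Gaussian noise **relative to the peak
amplitude** — the simplest defensible model for baseline-dominated
spectra — and a mandatory integer seed; the same truth and seed give
identical data, and a truth sidecar accompanies every written dataset.
Defaults mirror the study conditions the package targets: two-band EPR
at 3.485/9.636 GHz and 20 K; an 8-point uniform temperature grid over
8–60 K for the intensity × T series; 4.2 K Mössbauer spectra at fields
from 7.5 mT to several tesla, with optional two-species mixtures.

What the generator does *not* emulate: baseline drift, modulation
distortion, passage effects, source linewidth, absorber-thickness
saturation, or relaxation lineshapes. Recovery tests passing on these
synthetic data therefore demonstrate the correctness and
identifiability of the estimators under the stated noise model, not
robustness to instrumental artifacts.

Under those defaults the J-recovery problem (truth 40 cm⁻¹, 5% noise)
has an estimator spread of about 7% of J: single-seed recoveries
scatter accordingly, the median relative error over hundreds of seeds
is below 5%, and the 1σ intervals from the Jacobian cover the truth at
roughly the nominal rate (the finite 8-point design and nonlinearity
push coverage slightly below 68%).

## Numerical choices

* Diagonalization: LAPACK Hermitian solvers throughout; degenerate
  Kramers pairs at B = 0 are handled by summing expectations over the
  pair, which is basis-independent.
* Powder grids: octant igloo for EPR (default 400 knots); hemisphere
  for Mössbauer (default 100) because rotated hyperfine/EFG tensors
  break octant symmetry. Tests and the acceptance script use 30–60
  knots, where simulations are converged to well below the noise levels
  they carry.
* Optimization: bounded Levenberg–Marquardt (`minpack.lm`), residual
  norms monotone by construction; multi-start (8 seeded restarts,
  best residual wins, ties to the lowest seed) only where local minima
  are real, i.e. the Euler angles of the EPR problem. 1σ uncertainties
  come from the Jacobian at the solution; `profile_uncertainty()`
  provides conditional 1-D profiles and flags flat ones.
* Boltzmann populations use k_B = 0.695035 cm⁻¹ K⁻¹; levels below a
  10⁻⁴ population cutoff are dropped from spectra.
* Problem sizes in the shipped tests and acceptance script: 256–1024
  point spectra, 30–60 powder orientations, two Mössbauer fields
  (45 mT and 4 T), 300-replicate recovery statistics — all chosen so a
  full run is a desk-scale computation.

## Known limitations

* Isotropic exchange only: no antisymmetric (Dzyaloshinskii–Moriya) or
  dipolar inter-site terms, and a single J.
* First-order EPR resonance placement (no exact eigenfields); fine for
  A ≪ hν but not for strain-broadened or level-crossing regimes.
* Second-order (ZFS-mediated) corrections to projection coefficients
  are unmodelled; they matter at the few-percent level when D/J is not
  small.
* Mössbauer relaxation is slow-limit only; intermediate relaxation
  rates need a lineshape theory this package does not contain.
* No absolute intensity calibration (spins per mT, recoil-free
  fractions).
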