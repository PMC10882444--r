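# dimerspec

Spin-Hamiltonian simulation and fitting for exchange-coupled bimetallic
centres — the magnetic-spectroscopy toolbox behind combined EPR /
Mössbauer characterization of Fe(III)–Mn(III/IV) cores of the kind that
model the FeMn cofactors of class Ic ribonucleotide reductase and R2lox.
It is written for spectroscopists who need to connect three experiments
on one parameter set: multifrequency cw-EPR of the coupled ground
doublet, temperature/power-saturation determinations of the exchange
coupling, and variable-field ⁵⁷Fe Mössbauer spectra.

## What it computes

The central object is the dimer spin Hamiltonian (energies in cm⁻¹,
fields in T, hyperfine in MHz)

    H = J S1·S2  +  Σ_i [ S_i D_i S_i + μB B g_i S_i ]
                 +  Σ_n [ S A_n I_n − g_n μN B·I_n ]

with +J S₁·S₂, J > 0 antiferromagnetic. On top of it:

* **Projection algebra** between the coupled and site representations:
  c_i = [S(S+1)+S_i(S_i+1)−S_j(S_j+1)]/[2S(S+1)], so the S = 1/2 ground
  doublet of an S_Fe = 5/2 / S_Mn = 2 pair has (c_Fe, c_Mn) = (7/3, −4/3),
  g_c = 2 − (4/3)(g_Mn − 2), and A_Mn = −(3/4)A^C_Mn.
* **Powder cw-EPR simulation** of the coupled doublet with its six-line
  ⁵⁵Mn hyperfine pattern at arbitrary microwave frequency, with a
  simultaneous two-frequency least-squares fit (g, A, and the g∠A Euler
  rotation), plus effective g-values of Kramers doublets (rhombograms).
* **Exchange thermodynamics**: intensity×T curves from the Heisenberg
  ladder E(S) = (J/2)[S(S+1)−S₁(S₁+1)−S₂(S₂+1)] and J-fits from
  temperature series; Orbach fits P½(T) = aT + b/(exp(Δ/kT)−1) with
  Δ = J(S_min+1).
* **Variable-field ⁵⁷Fe Mössbauer simulation and fitting** for coupled
  dimers, including the option to diagonalize the ⁵⁵Mn nuclear spin
  together with the electronic system — at permanent-magnet fields
  (7.5–45 mT) the Mn hyperfine energy (0.0087 cm⁻¹ for A_iso = 260 MHz)
  is >10% of the electronic Zeeman splitting (~0.04 cm⁻¹) and visibly
  shrinks the apparent ⁵⁷Fe line splitting, while tesla-scale spectra are
  unaffected.
* **Synthetic-data generators** (seeded, with truth sidecars) for every
  experiment above, and the structural indices τ₅ = (β−α)/60° and
  metal-to-plane displacement for five-coordinate sites.

## Worked example

Map a fitted coupled-representation ⁵⁵Mn hyperfine tensor back to the
Mn(III) site:

```r
library(dimerspec)
site_A_from_coupled(c(215, 243, 341), c_site = -4/3)
#> <site_projection>
#>   A_coupled (MHz): 215, 243, 341
#>   c_site         : -1.333333
#>   A_site    (MHz): -161.25, -182.25, -255.75
#>   A_iso     (MHz): -199.75  -> -200 (rounded)
#>   A_SD      (MHz):  38.5,  17.5, -56.0
```

The isotropic part near −200 MHz is the Mn(III) fingerprint; the
traceless remainder is the spin-dipolar tensor. Recover an exchange
coupling from a synthetic intensity×T series of the S = 3/2 excited
multiplet (truth J = 40 cm⁻¹, 5% noise):

```r
exchange_ladder(5/2, 2, 40)
#>     S energy degeneracy
#> 1 0.5      0          2
#> 2 1.5     60          4
#> 3 2.5    160          6
#> 4 3.5    300          8
#> 5 4.5    480         10

td  <- generate_tempdep_dataset(J = 40, noise_sd = 0.05, seed = 1)
fit_exchange_tempdep(td$series)
#> <fit_result> converged | residual norm 0.0334155 | 17 evaluations
#>       estimate     sigma
#> J     39.69844 2.1436590
#> scale  1.01205 0.0707853
```

The S = 3/2 multiplet sits 3J/2 = 60 cm⁻¹ above the ground doublet and
J comes back within one standard error of the truth. Simulating the
low-field Mössbauer consequence of the Mn nucleus:

```r
dm <- exchange_dimer(
  spin_site("Fe", 5/2),
  spin_site("Mn", 2, nuclei = list(
    nuclear_coupling("55Mn", A = c(-161.25, -182.25, -255.75),
                     A_euler = c(73, 54, 76)))),
  J = 120)
st <- mossbauer_site(delta = 0.53, dEQ = -1.84, A_Fe = -20)
ex <- mossbauer_experiment(fields_T = 0.045)      # include_mn = FALSE
without_mn <- simulate_mossbauer(st, dm, ex)
ex$include_mn <- TRUE
with_mn <- simulate_mossbauer(st, dm, ex)
```

The two 45 mT spectra differ by >10% RMS of the peak absorption; at 4 T
they coincide to <0.1%.

A command-line wrapper ships in `inst/scripts/dimerspec`
(`project`, `geom`, `simulate-epr`, `simulate-moss`, `fit-tempdep`,
`fit-psat`, `gen`); example system files are under `inst/extdata/`.

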