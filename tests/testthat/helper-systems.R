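# Canonical spin systems used across the test files: the three
# oxo/hydroxo-bridged Fe(III)Mn(III) coupled-doublet parameter sets, and
# dimer/Moessbauer descriptions of the main species.

# Coupled-doublet EPR parameter sets (g, coupled 55Mn A in MHz, g/A Euler
# angles in degrees) with the site A_iso values they project to.
doublet_rows <- list(
  oxo   = list(g = c(2.042, 2.031, 2.007), A = c(215, 243, 341),
               euler = c(73, 54, 76), A_iso = -200,
               A_SD = c(39, 17, -57), J = 120),
  hydroxo = list(g = c(2.026, 2.024, 2.007), A = c(209, 255, 323),
               euler = c(90, 27, 62), A_iso = -197,
               A_SD = c(41, 5, -46), J = 40),
  protonated = list(g = c(2.037, 2.025, 2.008), A = c(202, 254, 327),
               euler = c(77, 53, 71), A_iso = -196,
               A_SD = c(44, 6, -50), J = 100)
)

make_doublet <- function(row) {
  coupled_doublet(g = row$g, A_Mn = row$A, euler_gA = row$euler)
}

# Fe(III)Mn(III) dimer carrying the site-representation 55Mn hyperfine
# tensor derived from the coupled fit (A_site = A_coupled / c_Mn).
make_femn_dimer <- function(J = 120, row = doublet_rows$oxo,
                            with_mn = TRUE) {
  cMn <- projection_coefficients(5/2, 2, 1/2)[2]
  nuc <- if (with_mn)
    list(nuclear_coupling("55Mn", A = row$A / cMn, A_euler = row$euler))
  else list()
  exchange_dimer(spin_site("Fe", 5/2),
                 spin_site("Mn", 2, nuclei = nuc), J = J)
}

# Published-style Moessbauer parameter set of the oxo-bridged species.
make_moss_site <- function(gamma = 0.3) {
  mossbauer_site(delta = 0.53, dEQ = -1.84, A_Fe = -20, gamma = gamma)
}

expect_hermitian <- function(H, tol = 1e-10) {
  nrm <- max(Mod(H))
  expect_lt(max(Mod(H - Conj(t(H)))), tol * max(nrm, 1))
}
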