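# Spin operator algebra, tensor rotation, Hamiltonian assembly.

test_that("spin matrices have the correct spectrum and algebra", {
  half <- spin_matrices(1/2)
  expect_equal(Re(diag(half$z)), c(1/2, -1/2))
  expect_equal(Re(half$x), matrix(c(0, 1/2, 1/2, 0), 2), ignore_attr = TRUE)

  expect_equal(sort(Re(diag(spin_matrices(2)$z))), -2:2)

  for (S in c(1/2, 1, 3/2, 5/2)) {
    sm <- spin_matrices(S)
    comm <- sm$x %*% sm$y - sm$y %*% sm$x - 1i * sm$z
    expect_lt(max(Mod(comm)), 1e-12)
    # Casimir S^2 = S(S+1)
    S2 <- sm$x %*% sm$x + sm$y %*% sm$y + sm$z %*% sm$z
    expect_equal(Re(diag(S2)), rep(S * (S + 1), 2 * S + 1), tolerance = 1e-12)
  }
})

test_that("non-half-integer spins are rejected with a useful message", {
  expect_error(spin_matrices(0.3), "0.3")
  expect_error(spin_matrices(-1), "non-negative")
  expect_error(spin_site("X", 0.7), "half-integer")
  expect_error(nuclear_coupling("55Mn", A = 1, I = 0.4, g_n = 1), "half-integer")
})

test_that("tensor rotation preserves eigenvalues and trace", {
  expect_equal(rotate_tensor(c(1, 2, 3), c(0, 0, 0)), diag(c(1, 2, 3)))

  set.seed(42)
  for (k in 1:10) {
    p <- rnorm(3, 0, 100)
    eul <- runif(3, -180, 360)
    M <- rotate_tensor(p, eul)
    expect_equal(sum(diag(M)), sum(p), tolerance = 1e-12)
    expect_equal(sort(eigen(M, symmetric = TRUE)$values), sort(p),
                 tolerance = 1e-9)
  }
  # fitted coupled-tensor components survive the frame rotation
  M <- rotate_tensor(c(215, 243, 341), c(73, 54, 76))
  expect_equal(sort(eigen(M, symmetric = TRUE)$values), c(215, 243, 341),
               tolerance = 1e-9)
})

test_that("rotation composed with its inverse is the identity", {
  eul <- c(73, 54, 76)
  R <- euler_matrix(eul)
  Rinv <- euler_matrix(c(-eul[3], -eul[2], -eul[1]))
  expect_equal(R %*% Rinv, diag(3), tolerance = 1e-12)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
})

test_that("exchange-only eigenvalues match the closed-form ladder", {
  spins <- c(1/2, 1, 3/2, 2, 5/2)
  for (S1 in spins) for (S2 in spins) {
    d <- exchange_dimer(spin_site("A", S1), spin_site("B", S2), J = 37.3)
    ev <- sort(Re(eigen(build_hamiltonian(d), symmetric = TRUE,
                        only.values = TRUE)$values))
    lad <- exchange_ladder(S1, S2, 37.3)
    expected <- sort(rep(lad$energy, lad$degeneracy))
    expect_equal(ev - min(ev), expected, tolerance = 1e-9)
  }
})

test_that("Hamiltonian dimensions, Hermiticity and trace bookkeeping", {
  d <- make_femn_dimer(J = 40)
  H <- build_hamiltonian(d)
  expect_equal(nrow(H), 30L)
  Hmn <- build_hamiltonian(d, include_nuclei = "55Mn")
  expect_equal(nrow(Hmn), 180L)

  set.seed(7)
  for (k in 1:5) {
    B <- rnorm(3, 0, 2)
    d2 <- exchange_dimer(
      spin_site("Fe", 5/2, g = runif(3, 1.9, 2.1), g_euler = runif(3, 0, 90),
                D = 0.5, E = 0.1),
      spin_site("Mn", 2, g = runif(3, 1.9, 2.1), D = -2, E = 0.3,
                nuclei = list(nuclear_coupling("55Mn", A = rnorm(3, -200, 30),
                                               A_euler = runif(3, 0, 90)))),
      J = 120)
    H <- build_hamiltonian(d2, B = B, include_nuclei = "55Mn")
    expect_hermitian(H)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev), Re(sum(diag(H))), tolerance = 1e-8)
  }
})

test_that("trivial limits of the Hamiltonian", {
  d <- exchange_dimer(spin_site("Fe", 5/2), spin_site("Mn", 2), J = 0)
  H <- build_hamiltonian(d)
  expect_lt(max(Mod(H)), 1e-14)

  # gap between the two lowest multiplets of the J = 40 ladder
  lad <- exchange_ladder(5/2, 2, 40)
  expect_equal(lad$energy[2] - lad$energy[1], 60)
})

test_that("unknown isotopes are rejected listing what is available", {
  d <- make_femn_dimer()
  expect_error(build_hamiltonian(d, include_nuclei = "63Cu"),
               "available.*55Mn")
  expect_error(build_hamiltonian(make_femn_dimer(with_mn = FALSE),
                                 include_nuclei = "55Mn"), "none")
})

test_that("Boltzmann weights behave", {
  expect_equal(boltzmann_weights(c(0, 60, 160), 1e9), rep(1/3, 3),
               tolerance = 1e-6)
  w <- boltzmann_weights(c(0, 60), 20)
  expect_equal(w[2] / w[1], exp(-60 / (0.695035 * 20)), tolerance = 1e-12)
  expect_equal(w[2] / w[1], 0.01335, tolerance = 1e-3)
  expect_equal(boltzmann_weights(c(5, 5, 5), 10), rep(1/3, 3))
  expect_equal(boltzmann_weights(c(0, 60), 20),
               boltzmann_weights(c(1000, 1060), 20))
  expect_equal(sum(boltzmann_weights(rnorm(10), 4.2)), 1)
  expect_error(boltzmann_weights(c(0, 1), 0), "> 0")
  expect_error(boltzmann_weights(c(0, 1), -5), "> 0")
})

test_that("unit table round trips and Moessbauer constants", {
  u <- unit_table()
  x <- c(-260, 1, 715.3)
  expect_equal(wavenumber_to_mhz(mhz_to_wavenumber(x)), x, tolerance = 1e-12)
  A_T <- convert_hyperfine(x, g_n = u$g_n_57Fe_gnd, from = "MHz")
  expect_equal(convert_hyperfine(A_T, g_n = u$g_n_57Fe_gnd, from = "T"), x,
               tolerance = 1e-12)
  expect_equal(mhz_to_mmps(mmps_to_mhz(x)), x, tolerance = 1e-12)
})

test_that("rhombicity outside the canonical range is rejected", {
  expect_error(spin_site("Mn", 2, D = 1, E = 0.5), "1/3")
  expect_silent(spin_site("Mn", 2, D = 0, E = 0.5))  # no ZFS, E ignored
})
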