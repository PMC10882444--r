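# Variable-field 57Fe Moessbauer simulation for exchange-coupled dimers.
#
# The electronic system (optionally including the 55Mn nuclear spin in the
# diagonalized space) sets the spin expectation <S_Fe> of each populated
# level; the 57Fe nucleus is then treated as a sub-problem per electronic
# level in the effective field B_eff = B_app + B_int, with
# B_int = -<S_Fe>.A_Fe in tesla (A in field units is the energy coupling
# divided by g_n(gnd) mu_N).  The asymmetry of the treatment is deliberate:
# the 57Fe hyperfine energy (~0.001 cm^-1) is far too small to act back on
# the electronic system, whereas the 55Mn coupling (~0.0087 cm^-1) is a
# sizeable fraction of the electronic Zeeman splitting at permanent-magnet
# fields (~0.04 cm^-1 at 45 mT) and must be diagonalized with it.

#' 57Fe Moessbauer site parameters
#'
#' @param delta Isomer shift (mm/s).
#' @param dEQ Quadrupole splitting (mm/s, signed).
#' @param eta EFG asymmetry parameter in [0, 1].
#' @param A_Fe 57Fe hyperfine tensor in tesla (signed); one value is
#'   recycled isotropically.
#' @param A_Fe_euler ZYZ Euler angles (degrees) of the A/EFG principal
#'   frame relative to the molecular frame.
#' @param gamma Lorentzian FWHM (mm/s).
#' @return Object of class `mossbauer_site`.
#' @export
#' @examples
#' mossbauer_site(delta = 0.53, dEQ = -1.84, A_Fe = -20)
mossbauer_site <- function(delta, dEQ, eta = 0, A_Fe = 0,
                           A_Fe_euler = c(0, 0, 0), gamma = 0.3) {
  stopifnot(eta >= 0, eta <= 1, gamma > 0)
  structure(list(delta = delta, dEQ = dEQ, eta = eta,
                 A_Fe = rep_len(as.numeric(A_Fe), 3L),
                 A_Fe_euler = A_Fe_euler, gamma = gamma),
            class = "mossbauer_site")
}

#' Moessbauer experiment description
#'
#' @param fields_T Applied fields (tesla).
#' @param temperature_K Sample temperature (default 4.2 K; the simulation
#'   assumes the slow-relaxation limit).
#' @param geometry Applied field `"perpendicular"` (default) or
#'   `"parallel"` to the gamma-beam.
#' @param velocity_range Velocity window `c(min, max)` in mm/s.
#' @param n_points Number of velocity points.
#' @param include_mn Diagonalize the 55Mn nuclear spin with the electronic
#'   system (requires a 55Mn coupling on the dimer).
#' @param n_orientations Powder-grid size over the hemisphere.
#' @return Object of class `mossbauer_experiment`.
#' @export
mossbauer_experiment <- function(fields_T, temperature_K = 4.2,
                                 geometry = c("perpendicular", "parallel"),
                                 velocity_range = c(-10, 10), n_points = 512,
                                 include_mn = FALSE, n_orientations = 100) {
  geometry <- match.arg(geometry)
  stopifnot(length(fields_T) >= 1L, temperature_K > 0,
            velocity_range[1] < velocity_range[2])
  structure(list(fields_T = fields_T, temperature_K = temperature_K,
                 geometry = geometry, velocity_range = velocity_range,
                 n_points = n_points, include_mn = include_mn,
                 n_orientations = n_orientations),
            class = "mossbauer_experiment")
}

# Precompute the field-independent and Zeeman parts of the dimer
# Hamiltonian so that per-orientation assembly is a cheap axpy.
.dimer_setup <- function(dimer, include_nuclei = character(), fe_site = 1L) {
  ops <- dimer_operators(dimer, include_nuclei)
  u <- .units
  H0 <- dimer$J * .dot3(ops$S1, ops$S2)
  sites <- list(dimer$site1, dimer$site2)
  Sops <- list(ops$S1, ops$S2)
  Z <- vector("list", 3L)
  for (k in 1:3) Z[[k]] <- matrix(0i, ops$n, ops$n)
  for (k in 1:2) {
    s <- sites[[k]]
    Rg <- euler_matrix(s$g_euler)
    gmat <- Rg %*% diag(s$g, 3, 3) %*% t(Rg)
    for (i in 1:3) for (j in 1:3)
      if (gmat[i, j] != 0) {
        Sj <- Sops[[k]][[c("x", "y", "z")[j]]]
        Z[[i]] <- Z[[i]] + u$mu_B * gmat[i, j] * Sj
      }
    if (s$D != 0 || s$E != 0) {
      Dp <- diag(c(-s$D / 3 + s$E, -s$D / 3 - s$E, 2 * s$D / 3), 3, 3)
      H0 <- H0 + .bilinear(Sops[[k]], Rg %*% Dp %*% t(Rg), Sops[[k]])
    }
  }
  for (nu in ops$nuclei) {
    s <- sites[[nu$site]]
    cpl <- nu$coupling
    Rg <- euler_matrix(s$g_euler)
    RA <- euler_matrix(cpl$A_euler)
    Amol <- Rg %*% RA %*% diag(cpl$A / u$MHz_per_cm1, 3, 3) %*% t(RA) %*% t(Rg)
    H0 <- H0 + .bilinear(Sops[[nu$site]], Amol, nu$I)
    cn <- -cpl$g_n * u$mu_N_MHz / u$MHz_per_cm1
    for (i in 1:3) Z[[i]] <- Z[[i]] + cn * nu$I[[c("x", "y", "z")[i]]]
  }
  list(H0 = H0, Z = Z, SFe = if (fe_site == 1L) ops$S1 else ops$S2, n = ops$n)
}

# Effective ground-multiplet (projected) analogue of .dimer_setup: the
# dimer is replaced by its ground total-spin manifold with projected g and
# 55Mn A tensors; <S_Fe> = c_Fe <S>.
.doublet_setup <- function(dimer, include_nuclei = character(),
                           fe_site = 1L) {
  u <- .units
  S1 <- dimer$site1$S; S2 <- dimer$site2$S
  Sg <- abs(S1 - S2)
  if (Sg <= 0) stop("ground multiplet has S = 0: no projected model exists")
  co <- projection_coefficients(S1, S2, Sg)
  cFe <- if (fe_site == 1L) co[1] else co[2]
  sites <- list(dimer$site1, dimer$site2)
  gmat <- matrix(0, 3, 3)
  for (k in 1:2) {
    Rg <- euler_matrix(sites[[k]]$g_euler)
    gmat <- gmat + co[k] * Rg %*% diag(sites[[k]]$g, 3, 3) %*% t(Rg)
  }
  nuc <- list()
  for (k in 1:2) for (cpl in sites[[k]]$nuclei)
    if (cpl$isotope %in% include_nuclei)
      nuc[[length(nuc) + 1L]] <- list(site = k, coupling = cpl)
  dims <- as.integer(round(c(2 * Sg + 1,
                             vapply(nuc, function(z) 2 * z$coupling$I + 1, 0))))
  mk <- function(S, k) lapply(spin_matrices(S), .embed, k = k, dims = dims)
  Sop <- mk(Sg, 1L)
  n <- prod(dims)
  H0 <- matrix(0i, n, n)
  Z <- lapply(1:3, function(i) matrix(0i, n, n))
  for (i in 1:3) for (j in 1:3)
    if (gmat[i, j] != 0)
      Z[[i]] <- Z[[i]] + u$mu_B * gmat[i, j] * Sop[[c("x", "y", "z")[j]]]
  if (length(nuc)) for (jn in seq_along(nuc)) {
    s <- sites[[nuc[[jn]]$site]]
    cpl <- nuc[[jn]]$coupling
    Iop <- mk(cpl$I, 1L + jn)
    Rg <- euler_matrix(s$g_euler)
    RA <- euler_matrix(cpl$A_euler)
    Amol <- co[nuc[[jn]]$site] *
      Rg %*% RA %*% diag(cpl$A / u$MHz_per_cm1, 3, 3) %*% t(RA) %*% t(Rg)
    H0 <- H0 + .bilinear(Sop, Amol, Iop)
    cn <- -cpl$g_n * u$mu_N_MHz / u$MHz_per_cm1
    for (i in 1:3) Z[[i]] <- Z[[i]] + cn * Iop[[c("x", "y", "z")[i]]]
  }
  SFe <- lapply(Sop, function(M) cFe * M)
  list(H0 = H0, Z = Z, SFe = SFe, n = n)
}

# Populated eigenstates and Fe-site spin expectations at one field vector.
.electronic_states <- function(setup, Bvec, temperature, cutoff = 1e-4) {
  H <- setup$H0 + Bvec[1] * setup$Z[[1]] + Bvec[2] * setup$Z[[2]] +
    Bvec[3] * setup$Z[[3]]
  ev <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  E <- Re(ev$values[setup$n:1])          # ascending
  V <- ev$vectors[, setup$n:1, drop = FALSE]
  w <- boltzmann_weights(E, temperature)
  keep <- which(w > cutoff)
  Vk <- V[, keep, drop = FALSE]
  Sx <- Re(colSums(Conj(Vk) * (setup$SFe$x %*% Vk)))
  Sy <- Re(colSums(Conj(Vk) * (setup$SFe$y %*% Vk)))
  Sz <- Re(colSums(Conj(Vk) * (setup$SFe$z %*% Vk)))
  list(energy = E[keep], w = w[keep] / sum(w[keep]),
       S = rbind(Sx, Sy, Sz))
}

#' Fe-site spin expectation values of the populated levels
#'
#' Diagonalizes the dimer spin Hamiltonian at one applied field and
#' returns, for every thermally populated level, its Boltzmann weight and
#' the expectation of the iron-site spin operator.  With
#' `include_mn_nucleus = TRUE` the 55Mn nuclear spin is part of the
#' diagonalized space, so the levels carry mixed electron-nuclear
#' character and the distribution of |<S_Fe>| broadens at low field; at
#' high field the electronic Zeeman term dominates and the spread
#' collapses.
#'
#' @param dimer An [exchange_dimer()] whose first site is the Fe site by
#'   default.
#' @param B Applied field: scalar (along molecular z) or 3-vector, tesla.
#' @param temperature Temperature in K.
#' @param include_mn_nucleus Include the 55Mn nucleus in the diagonalized
#'   space.
#' @param fe_site Index (1 or 2) of the iron site in the dimer.
#' @param cutoff Minimum Boltzmann weight for a level to be reported.
#' @return Data frame with columns `energy` (cm^-1), `weight`, `Sx`, `Sy`,
#'   `Sz` (molecular frame).
#' @export
#' @examples
#' d <- exchange_dimer(spin_site("Fe", 5/2), spin_site("Mn", 2), J = 120)
#' spin_expectation_fe(d, B = 4, temperature = 4.2)   # <S_Fe,z> near -/+ 7/6
spin_expectation_fe <- function(dimer, B, temperature = 4.2,
                                include_mn_nucleus = FALSE, fe_site = 1L,
                                cutoff = 1e-4) {
  if (length(B) == 1L) B <- c(0, 0, B)
  inc <- if (include_mn_nucleus) "55Mn" else character()
  setup <- .dimer_setup(dimer, inc, fe_site)
  st <- .electronic_states(setup, B, temperature, cutoff)
  data.frame(energy = st$energy, weight = st$w,
             Sx = st$S[1, ], Sy = st$S[2, ], Sz = st$S[3, ])
}

# Clebsch-Gordan amplitudes <3/2 m_e | T^1_q | 1/2 m_g> for the 14.4 keV
# M1 transition, in the m-basis ordering m = I, ..., -I.
.cg_q <- local({
  Tq <- list()
  Tp <- matrix(0, 4, 2); Tp[1, 1] <- 1;           Tp[2, 2] <- sqrt(1/3)
  T0 <- matrix(0, 4, 2); T0[2, 1] <- sqrt(2/3);   T0[3, 2] <- sqrt(2/3)
  Tm <- matrix(0, 4, 2); Tm[3, 1] <- sqrt(1/3);   Tm[4, 2] <- 1
  list(p = Tp, z = T0, m = Tm)
})

# 57Fe nuclear sub-problem for one electronic level: returns the 8 M1
# transition lines (velocity in mm/s, relative intensity) for effective
# field Beff (tesla, molecular frame) and the c2 = <cos^2(theta)> between
# B_eff and the gamma-beam.
.fe_lines <- function(site, Beff, c2) {
  u <- .units
  b <- sqrt(sum(Beff^2))
  if (b > 1e-12) {
    zq <- Beff / b
  } else {
    zq <- c(0, 0, 1); c2 <- 1/3
  }
  a <- if (abs(zq[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(zq[2] * a[3] - zq[3] * a[2], zq[3] * a[1] - zq[1] * a[3],
          zq[1] * a[2] - zq[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(zq[2] * e1[3] - zq[3] * e1[2], zq[3] * e1[1] - zq[1] * e1[3],
          zq[1] * e1[2] - zq[2] * e1[1])
  Rq <- rbind(e1, e2, zq)                    # molecular -> quantization
  Ig <- spin_matrices(1/2)
  Ie <- spin_matrices(3/2)
  Hg <- -u$g_n_57Fe_gnd * u$mu_N_MHz * b * Ig$z
  He <- -u$g_n_57Fe_exc * u$mu_N_MHz * b * Ie$z
  if (site$dEQ != 0) {
    C <- site$dEQ * u$mmps_to_MHz / sqrt(1 + site$eta^2 / 3)   # eQVzz/2, MHz
    Pp <- (C / 6) * diag(c(-1 + site$eta, -1 - site$eta, 2), 3, 3)
    RA <- euler_matrix(site$A_Fe_euler)
    Pq <- Rq %*% RA %*% Pp %*% t(RA) %*% t(Rq)
    He <- He + .bilinear(Ie, Pq, Ie)
  }
  eg <- eigen((Hg + Conj(t(Hg))) / 2, symmetric = TRUE)
  ee <- eigen((He + Conj(t(He))) / 2, symmetric = TRUE)
  wq <- c(p = (3/4) * (1 + c2), z = (3/2) * (1 - c2), m = (3/4) * (1 + c2))
  v <- outer(Re(ee$values), Re(eg$values), "-") / u$mmps_to_MHz + site$delta
  int <- matrix(0, 4, 2)
  for (q in names(.cg_q)) {
    M <- Conj(t(ee$vectors)) %*% .cg_q[[q]] %*% eg$vectors
    int <- int + wq[[q]] * Mod(M)^2
  }
  cbind(v = as.vector(v), int = as.vector(int))
}

# cos^2 between the gamma-beam and B_eff, averaged over the azimuth of the
# molecule about the applied-field direction.  n = unit applied-field
# direction (molecular frame), u = unit B_eff (molecular frame), chi =
# angle between beam and applied field in the lab.
.beam_cos2 <- function(u_vec, n_vec, geometry) {
  cos2chi <- if (geometry == "parallel") 1 else 0
  un <- sum(u_vec * n_vec)
  cos2chi * un^2 + 0.5 * (1 - cos2chi) * (1 - un^2)
}

# One species, one field: accumulate all transition lines over the powder.
.moss_lines_field <- function(site, elec, grid, B_T) {
  u <- .units
  RA <- euler_matrix(site$A_Fe_euler)
  Amol <- RA %*% diag(site$A_Fe, 3, 3) %*% t(RA)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nvec <- c(grid$x[i], grid$y[i], grid$z[i])
    st <- elec[[i]]
    rows <- vector("list", length(st$w))
    for (k in seq_along(st$w)) {
      Bint <- -as.numeric(Amol %*% st$S[, k])
      Beff <- B_T * nvec + Bint
      bu <- sqrt(sum(Beff^2))
      uvec <- if (bu > 1e-12) Beff / bu else nvec
      c2 <- if (B_T > 1e-12 || bu > 1e-12)
        .beam_cos2(uvec, nvec, attr(elec, "geometry")) else 1/3
      ln <- .fe_lines(site, Beff, c2)
      ln[, "int"] <- ln[, "int"] * st$w[k] * grid$w[i]
      rows[[k]] <- ln
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

.moss_convolve <- function(lines, vgrid, gamma) {
  hw <- gamma / 2
  Z <- outer(vgrid, lines[, "v"], "-")
  L <- (hw / pi) / (Z^2 + hw^2)
  as.numeric(L %*% lines[, "int"])
}

# Electronic precomputation for one species over all fields/orientations.
.moss_electronic <- function(dimer, expt, electronic, fe_site,
                             cutoff = 1e-4) {
  inc <- if (expt$include_mn) "55Mn" else character()
  setup <- if (electronic == "full") .dimer_setup(dimer, inc, fe_site)
           else .doublet_setup(dimer, inc, fe_site)
  grid <- powder_grid(expt$n_orientations, "hemisphere")
  lapply(expt$fields_T, function(B_T) {
    el <- lapply(seq_len(nrow(grid)), function(i)
      .electronic_states(setup, B_T * c(grid$x[i], grid$y[i], grid$z[i]),
                         expt$temperature_K, cutoff))
    attr(el, "geometry") <- expt$geometry
    attr(el, "grid") <- grid
    el
  })
}

#' Simulate variable-field 57Fe Moessbauer spectra of a coupled dimer
#'
#' For each applied field and powder orientation the electronic system
#' (optionally including the 55Mn nuclear spin) is diagonalized, and each
#' populated level contributes an 8-line 57Fe pattern computed in its
#' effective field; lines carry Clebsch-Gordan M1 intensities with the
#' angular weighting of the chosen field geometry and are convolved with a
#' Lorentzian of FWHM `gamma`.  Multi-species samples are fraction-weighted
#' sums.
#'
#' @param site A [mossbauer_site()] (ignored when `components` is given).
#' @param dimer An [exchange_dimer()]; its first site is taken as Fe.
#' @param expt A [mossbauer_experiment()].
#' @param electronic `"full"` (diagonalize the complete dimer space) or
#'   `"doublet"` (projected ground-multiplet model, valid in the
#'   strong-exchange limit).
#' @param components Optional list of `list(site=, dimer=, fraction=)` for
#'   mixtures; fractions must sum to 1.
#' @param fe_site Index of the iron site within each dimer.
#' @return Named list of [spectrum_data()] objects (ordinate: absorption,
#'   arbitrary units; total area is conserved across fields), one per
#'   applied field, named by the field in tesla.
#' @export
simulate_mossbauer <- function(site, dimer, expt, electronic = c("full",
                               "doublet"), components = NULL, fe_site = 1L) {
  electronic <- match.arg(electronic)
  stopifnot(inherits(expt, "mossbauer_experiment"))
  if (is.null(components))
    components <- list(list(site = site, dimer = dimer, fraction = 1))
  fr <- vapply(components, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("species fractions must sum to 1")
  vgrid <- seq(expt$velocity_range[1], expt$velocity_range[2],
               length.out = expt$n_points)
  total <- vector("list", length(expt$fields_T))
  for (ci in seq_along(components)) {
    cmp <- components[[ci]]
    stopifnot(inherits(cmp$site, "mossbauer_site"),
              inherits(cmp$dimer, "exchange_dimer"))
    elec <- .moss_electronic(cmp$dimer, expt, electronic, fe_site)
    for (fi in seq_along(expt$fields_T)) {
      lines <- .moss_lines_field(cmp$site, elec[[fi]],
                                 attr(elec[[fi]], "grid"),
                                 expt$fields_T[fi])
      y <- cmp$fraction * .moss_convolve(lines, vgrid, cmp$site$gamma)
      total[[fi]] <- if (is.null(total[[fi]])) y else total[[fi]] + y
      clip <- cmp$fraction * sum(lines[, "int"]) -
        sum(lines[, "int"][lines[, "v"] >= vgrid[1] &
                             lines[, "v"] <= vgrid[length(vgrid)]]) *
        cmp$fraction
      if (clip > 0.01 * cmp$fraction * sum(lines[, "int"]))
        warning("more than 1% of the absorption falls outside the ",
                "velocity range at B = ", expt$fields_T[fi], " T")
    }
  }
  out <- lapply(seq_along(expt$fields_T), function(fi)
    spectrum_data(vgrid, total[[fi]], kind = "velocity",
                  meta = list(field_T = expt$fields_T[fi],
                              temperature_K = expt$temperature_K,
                              include_mn = as.integer(expt$include_mn),
                              geometry = expt$geometry)))
  names(out) <- format(expt$fields_T)
  out
}

#' Simultaneous multi-field Moessbauer fit
#'
#' Least-squares fit of the site parameters (isomer shift, quadrupole
#' splitting, isotropic 57Fe A-tensor, optionally the linewidth and a
#' minor-species fraction) against spectra recorded at several applied
#' fields.  The 55Mn hyperfine tensor, if present on the dimer, is held
#' fixed (taken from EPR) and is never floated.  The electronic problem is
#' independent of all floated parameters and is diagonalized once, so each
#' optimizer iteration only redoes the fast nuclear stage.  Per-spectrum
#' amplitude scales are profiled out analytically.
#'
#' @param spectra List of [spectrum_data()] objects carrying `field_T`
#'   metadata.
#' @param dimer An [exchange_dimer()] describing the main species.
#' @param guess A [mossbauer_site()] starting point for the main species.
#' @param float Character subset of `c("delta", "dEQ", "A_iso", "gamma",
#'   "fraction")` to optimize.
#' @param minor Optional fixed minor species `list(site=, dimer=)` whose
#'   `fraction` may be floated.
#' @param fraction Starting minor-species fraction.
#' @param expt Optional [mossbauer_experiment()] template; fields and
#'   velocity grids are taken from the spectra.
#' @param electronic Electronic model, as in [simulate_mossbauer()].
#' @param n_orientations Powder-grid size used during fitting.
#' @return A [fit_result()].
#' @export
fit_mossbauer <- function(spectra, dimer, guess,
                          float = c("delta", "dEQ", "A_iso"), minor = NULL,
                          fraction = 0.15, expt = NULL,
                          electronic = c("full", "doublet"),
                          n_orientations = 60) {
  electronic <- match.arg(electronic)
  stopifnot(length(spectra) >= 1L, inherits(guess, "mossbauer_site"))
  fields <- vapply(spectra, function(s) {
    f <- s$meta$field_T
    if (is.null(f)) stop("spectrum lacks field_T metadata")
    as.numeric(f)
  }, 0)
  if (max(fields) < 0.02 && !("A_iso" %in% float))
    warning("all applied fields are below 20 mT: the sign of dEQ is ",
            "not identifiable")
  if (is.null(expt))
    expt <- mossbauer_experiment(fields_T = fields,
                                 n_orientations = n_orientations)
  expt$fields_T <- fields
  expt$n_orientations <- n_orientations
  elec_main <- .moss_electronic(dimer, expt, electronic, 1L)
  elec_minor <- if (!is.null(minor))
    .moss_electronic(minor$dimer, expt, electronic, 1L)
  p0 <- c(delta = guess$delta, dEQ = guess$dEQ, A_iso = mean(guess$A_Fe),
          gamma = guess$gamma, fraction = fraction)
  free <- intersect(c("delta", "dEQ", "A_iso", "gamma", "fraction"), float)
  if (!is.null(minor) && !("fraction" %in% free)) free <- c(free, "fraction")
  lower <- c(delta = -3, dEQ = -8, A_iso = -60, gamma = 0.05, fraction = 0)
  upper <- c(delta = 3, dEQ = 8, A_iso = 60, gamma = 2, fraction = 1)
  ymat <- lapply(spectra, function(s) s$y)
  vgrids <- lapply(spectra, function(s) s$x)
  model_y <- function(p, fi) {
    stf <- guess
    stf$delta <- p[["delta"]]; stf$dEQ <- p[["dEQ"]]
    stf$A_Fe <- rep(p[["A_iso"]], 3L); stf$gamma <- p[["gamma"]]
    frac <- if (!is.null(minor)) p[["fraction"]] else 0
    lines <- .moss_lines_field(stf, elec_main[[fi]],
                               attr(elec_main[[fi]], "grid"), fields[fi])
    y <- (1 - frac) * .moss_convolve(lines, vgrids[[fi]], stf$gamma)
    if (!is.null(minor)) {
      ln2 <- .moss_lines_field(minor$site, elec_minor[[fi]],
                               attr(elec_minor[[fi]], "grid"), fields[fi])
      y <- y + frac * .moss_convolve(ln2, vgrids[[fi]], minor$site$gamma)
    }
    y
  }
  fn <- function(pf) {
    p <- p0; p[free] <- pf
    unlist(lapply(seq_along(spectra), function(fi) {
      yh <- model_y(p, fi)
      sc <- sum(yh * ymat[[fi]]) / sum(yh^2)   # analytic amplitude
      sc * yh - ymat[[fi]]
    }))
  }
  fit <- .lm_fit(fn, p0[free], lower = lower[free], upper = upper[free],
                 info = list(fields_T = fields, electronic = electronic,
                             fixed = p0[setdiff(names(p0), free)]))
  fit
}
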