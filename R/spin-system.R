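# Spin-system containers and Hamiltonian assembly.

.known_isotopes <- data.frame(
  isotope = c("55Mn", "57Fe"),
  I       = c(5/2, 1/2),
  g_n     = c(1.3819, 0.18121),
  stringsAsFactors = FALSE
)

#' Nuclear hyperfine coupling attached to a spin site
#'
#' @param isotope Isotope label, e.g. `"55Mn"` or `"57Fe"`.  For known
#'   isotopes `I` and `g_n` default to tabulated values.
#' @param A Three principal hyperfine values, or one value recycled
#'   isotropically.
#' @param A_unit `"MHz"` or `"T"`; tesla values are converted to MHz with
#'   `g_n` on construction.
#' @param A_euler ZYZ Euler angles (degrees) rotating A relative to the
#'   site g-tensor frame.
#' @param I Nuclear spin (half-integer); required for unknown isotopes.
#' @param g_n Nuclear g-factor; required for unknown isotopes or for unit
#'   conversion.
#' @return Object of class `nuclear_coupling`.
#' @export
#' @examples
#' nuclear_coupling("55Mn", A = c(215, 243, 341))
nuclear_coupling <- function(isotope, A, A_unit = c("MHz", "T"),
                             A_euler = c(0, 0, 0), I = NULL, g_n = NULL) {
  A_unit <- match.arg(A_unit)
  row <- match(isotope, .known_isotopes$isotope)
  if (is.null(I)) {
    if (is.na(row)) stop("unknown isotope '", isotope, "': supply I and g_n")
    I <- .known_isotopes$I[row]
  }
  if (is.null(g_n)) {
    if (is.na(row)) stop("unknown isotope '", isotope, "': supply g_n")
    g_n <- .known_isotopes$g_n[row]
  }
  if (abs(2 * I - round(2 * I)) > 1e-9 || I < 0)
    stop("nuclear spin I must be a non-negative half-integer, got ", I)
  A <- rep_len(as.numeric(A), 3L)
  if (A_unit == "T") A <- convert_hyperfine(A, g_n, from = "T")
  structure(list(isotope = isotope, I = I, A = A, A_euler = A_euler,
                 g_n = g_n), class = "nuclear_coupling")
}

#' One paramagnetic metal site
#'
#' @param label Site name (e.g. `"Fe"`, `"Mn"`).
#' @param S Electronic spin; 2S must be a non-negative integer.
#' @param g Three principal g-values (one value is recycled).
#' @param g_euler ZYZ Euler angles (degrees) of the g/ZFS principal frame
#'   relative to the molecular frame.
#' @param D,E Axial and rhombic zero-field splitting (cm^-1).  The
#'   canonical range |E/D| <= 1/3 is enforced when D is nonzero.
#' @param nuclei List of [nuclear_coupling()] objects.
#' @return Object of class `spin_site`.
#' @export
#' @examples
#' spin_site("Fe", 5/2)
#' spin_site("Mn", 2, g = c(1.98, 1.98, 1.97),
#'           nuclei = list(nuclear_coupling("55Mn", A = -200)))
spin_site <- function(label, S, g = c(2, 2, 2), g_euler = c(0, 0, 0),
                      D = 0, E = 0, nuclei = list()) {
  if (abs(2 * S - round(2 * S)) > 1e-9 || S < 0)
    stop("S must be a non-negative half-integer, got ", S)
  if (D != 0 && abs(E / D) > 1/3 + 1e-12)
    stop("|E/D| must be <= 1/3 (canonical rhombicity), got ", format(E / D))
  if (length(nuclei) && !all(vapply(nuclei, inherits, TRUE, "nuclear_coupling")))
    stop("nuclei must be a list of nuclear_coupling objects")
  structure(list(label = label, S = S, g = rep_len(as.numeric(g), 3L),
                 g_euler = g_euler, D = D, E = E, nuclei = nuclei),
            class = "spin_site")
}

#' Two spin sites joined by isotropic Heisenberg exchange
#'
#' Exchange convention \eqn{H = +J\, S_1 \cdot S_2} with J in cm^-1; J > 0
#' is antiferromagnetic and puts the minimal total spin lowest.
#'
#' @param site1,site2 [spin_site()] objects.
#' @param J Exchange coupling constant (cm^-1).
#' @return Object of class `exchange_dimer`.
#' @export
#' @examples
#' d <- exchange_dimer(spin_site("Fe", 5/2), spin_site("Mn", 2), J = 120)
exchange_dimer <- function(site1, site2, J) {
  stopifnot(inherits(site1, "spin_site"), inherits(site2, "spin_site"),
            is.finite(J))
  structure(list(site1 = site1, site2 = site2, J = J),
            class = "exchange_dimer")
}

#' @export
print.exchange_dimer <- function(x, ...) {
  cat(sprintf("<exchange_dimer> %s (S=%g) -- J = %g cm^-1 -- %s (S=%g)\n",
              x$site1$label, x$site1$S, x$J, x$site2$label, x$site2$S))
  for (s in list(x$site1, x$site2)) {
    if (length(s$nuclei))
      cat(sprintf("  %s nuclei: %s\n", s$label,
                  paste(vapply(s$nuclei, `[[`, "", "isotope"), collapse = ", ")))
  }
  invisible(x)
}

# Embed an operator acting on sub-space k of a tensor-product space.
.embed <- function(op, k, dims) {
  M <- if (k == 1L) op else diag(dims[1]) + 0i
  if (length(dims) > 1L) for (j in 2:length(dims))
    M <- M %x% (if (j == k) op else diag(dims[j]) + 0i)
  M
}

#' Product-space operators for an exchange dimer
#'
#' Builds the site spin operators (and nuclear spin operators for the
#' requested isotopes) embedded in the full tensor-product Hilbert space,
#' ordered site1 (x) site2 (x) nuclei.
#'
#' @param dimer An [exchange_dimer()].
#' @param include_nuclei Character vector of isotope labels to place in the
#'   space (e.g. `"55Mn"`); must exist on the sites.
#' @return List with `S1`, `S2` (each a list of x/y/z matrices), `nuclei`
#'   (per included nucleus: operators, site index, coupling), `dims`, and
#'   total dimension `n`.
#' @export
dimer_operators <- function(dimer, include_nuclei = character()) {
  stopifnot(inherits(dimer, "exchange_dimer"))
  sites <- list(dimer$site1, dimer$site2)
  nuc <- list()
  for (k in 1:2) for (cpl in sites[[k]]$nuclei)
    if (cpl$isotope %in% include_nuclei)
      nuc[[length(nuc) + 1L]] <- list(site = k, coupling = cpl)
  found <- vapply(nuc, function(z) z$coupling$isotope, "")
  missing <- setdiff(include_nuclei, found)
  if (length(missing)) {
    avail <- unlist(lapply(sites, function(s)
      vapply(s$nuclei, `[[`, "", "isotope")))
    stop("isotope(s) not present on any site: ",
         paste(missing, collapse = ", "), "; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  dims <- c(2 * sites[[1]]$S + 1, 2 * sites[[2]]$S + 1,
            vapply(nuc, function(z) 2 * z$coupling$I + 1, 0))
  dims <- as.integer(round(dims))
  mk <- function(S, k) {
    sm <- spin_matrices(S)
    lapply(sm, .embed, k = k, dims = dims)
  }
  ops <- list(S1 = mk(sites[[1]]$S, 1L), S2 = mk(sites[[2]]$S, 2L),
              nuclei = list(), dims = dims, n = prod(dims))
  if (length(nuc)) for (j in seq_along(nuc)) {
    ops$nuclei[[j]] <- list(site = nuc[[j]]$site, coupling = nuc[[j]]$coupling,
                            I = mk(nuc[[j]]$coupling$I, 2L + j))
  }
  ops
}

.dot3 <- function(a, b) a$x %*% b$x + a$y %*% b$y + a$z %*% b$z

# S . M . T for operator triples S, T and a 3x3 numeric matrix M
.bilinear <- function(Sop, M, Top) {
  H <- matrix(0i, nrow(Sop$x), ncol(Sop$x))
  S3 <- list(Sop$x, Sop$y, Sop$z); T3 <- list(Top$x, Top$y, Top$z)
  for (i in 1:3) for (j in 1:3)
    if (M[i, j] != 0) H <- H + M[i, j] * (S3[[i]] %*% T3[[j]])
  H
}

#' Assemble the spin Hamiltonian of an exchange-coupled dimer
#'
#' \deqn{H = J S_1 \cdot S_2 + \sum_i [S_i D_i S_i + \mu_B B g_i S_i]
#'       + \sum_n [S \cdot A_n \cdot I_n - g_n \mu_N B \cdot I_n]}
#' in cm^-1, with the zero-field-splitting and g tensors of each site
#' sharing that site's principal frame (`g_euler`) and each hyperfine
#' tensor rotated by its own `A_euler` relative to the site frame.  The
#' nuclear Zeeman term is retained even though it is negligible at the
#' fields of interest.
#'
#' @inheritParams dimer_operators
#' @param B Applied magnetic field, 3-vector in tesla (a scalar is taken
#'   along z).
#' @return Hermitian complex matrix in cm^-1 of dimension
#'   \eqn{(2S_1+1)(2S_2+1)\prod(2I+1)}, with the operator set attached as
#'   attribute `"operators"`.
#' @export
#' @examples
#' d <- exchange_dimer(spin_site("Fe", 5/2), spin_site("Mn", 2), J = 40)
#' H <- build_hamiltonian(d)
#' range(Re(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
build_hamiltonian <- function(dimer, B = c(0, 0, 0),
                              include_nuclei = character()) {
  if (length(B) == 1L) B <- c(0, 0, B)
  stopifnot(length(B) == 3L, all(is.finite(B)))
  ops <- dimer_operators(dimer, include_nuclei)
  u <- .units
  H <- dimer$J * .dot3(ops$S1, ops$S2)
  sites <- list(dimer$site1, dimer$site2)
  Sops <- list(ops$S1, ops$S2)
  for (k in 1:2) {
    s <- sites[[k]]
    Rg <- euler_matrix(s$g_euler)
    gmat <- Rg %*% diag(s$g, 3, 3) %*% t(Rg)
    # electronic Zeeman: mu_B * B . g . S
    bg <- u$mu_B * as.numeric(B %*% gmat)
    H <- H + bg[1] * Sops[[k]]$x + bg[2] * Sops[[k]]$y + bg[3] * Sops[[k]]$z
    if (s$D != 0 || s$E != 0) {
      Dp <- diag(c(-s$D / 3 + s$E, -s$D / 3 - s$E, 2 * s$D / 3), 3, 3)
      H <- H + .bilinear(Sops[[k]], Rg %*% Dp %*% t(Rg), Sops[[k]])
    }
  }
  for (nu in ops$nuclei) {
    s <- sites[[nu$site]]
    cpl <- nu$coupling
    Rg <- euler_matrix(s$g_euler)
    RA <- euler_matrix(cpl$A_euler)
    Amol <- Rg %*% RA %*% diag(cpl$A / u$MHz_per_cm1, 3, 3) %*% t(RA) %*% t(Rg)
    H <- H + .bilinear(Sops[[nu$site]], Amol, nu$I)
    bn <- -cpl$g_n * (u$mu_N_MHz / u$MHz_per_cm1) * B
    H <- H + bn[1] * nu$I$x + bn[2] * nu$I$y + bn[3] * nu$I$z
  }
  H <- (H + Conj(t(H))) / 2
  attr(H, "operators") <- ops
  H
}

#' Boltzmann population weights
#'
#' @param energies Level energies in cm^-1.
#' @param temperature Temperature in K (> 0).
#' @return Non-negative weights summing to 1; invariant under a uniform
#'   energy shift.
#' @export
#' @examples
#' boltzmann_weights(c(0, 60), 20)   # upper level ~1.3% relative factor
boltzmann_weights <- function(energies, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 K, got ", format(temperature))
  w <- exp(-(energies - min(energies)) / (.units$k_B * temperature))
  w / sum(w)
}
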