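# Powder cw-EPR simulation for the coupled S = 1/2 doublet with 55Mn
# hyperfine structure, and effective g-values of Kramers doublets.

#' Effective ground-doublet description of a coupled dimer
#'
#' In the strong-exchange limit the ground manifold of an
#' antiferromagnetically coupled S_Fe = 5/2 / S_Mn = 2 pair is an S = 1/2
#' doublet described by a g-tensor, a 55Mn hyperfine tensor, and the ZYZ
#' Euler rotation of A relative to g.
#'
#' @param g Three principal g-values.
#' @param A_Mn Three 55Mn hyperfine components in MHz (coupled
#'   representation; magnitudes as fitted).
#' @param euler_gA Euler angles (degrees) rotating A relative to g.
#' @param I_Mn Nuclear spin of the split nucleus (5/2 for 55Mn).
#' @return Object of class `coupled_doublet`.
#' @export
#' @examples
#' coupled_doublet(g = c(2.042, 2.031, 2.007), A_Mn = c(215, 243, 341),
#'                 euler_gA = c(73, 54, 76))
coupled_doublet <- function(g, A_Mn = c(0, 0, 0), euler_gA = c(0, 0, 0),
                            I_Mn = 5/2) {
  structure(list(g = rep_len(as.numeric(g), 3L),
                 A_Mn = rep_len(as.numeric(A_Mn), 3L),
                 euler_gA = rep_len(as.numeric(euler_gA), 3L), I_Mn = I_Mn),
            class = "coupled_doublet")
}

#' cw-EPR experiment description
#'
#' @param frequency_GHz Microwave frequency (> 0).
#' @param temperature_K Sample temperature (default 20 K).
#' @param field_range_mT Swept-field range `c(min, max)` in mT.
#' @param n_points Number of field points.
#' @param linewidth_mT Gaussian FWHM along each g principal axis (mT; a
#'   scalar is recycled).
#' @param n_orientations Powder-grid size (>= 16).
#' @param derivative If `TRUE` (default) return the first-derivative
#'   spectrum, as recorded by field modulation.
#' @return Object of class `epr_experiment`.
#' @export
epr_experiment <- function(frequency_GHz, temperature_K = 20,
                           field_range_mT = c(250, 450), n_points = 1024,
                           linewidth_mT = 3, n_orientations = 400,
                           derivative = TRUE) {
  stopifnot(frequency_GHz > 0, field_range_mT[1] < field_range_mT[2],
            n_orientations >= 16)
  structure(list(frequency_GHz = frequency_GHz, temperature_K = temperature_K,
                 field_range_mT = field_range_mT, n_points = n_points,
                 linewidth_mT = rep_len(linewidth_mT, 3L),
                 n_orientations = n_orientations, derivative = derivative),
            class = "epr_experiment")
}

#' Simulate a powder cw-EPR spectrum of the coupled doublet
#'
#' Field-swept powder simulation for an effective S = 1/2 system with one
#' hyperfine-coupled nucleus.  For each orientation n of the field in the
#' g principal frame, the electronic resonance field follows
#' \eqn{h\nu = g(n) \mu_B B_0} with \eqn{g(n)^2 = n^T g^2 n}, and the
#' 2I + 1 nuclear lines are placed by first-order perturbation theory with
#' the orientation-dependent splitting
#' \eqn{a(n) = |A G n| / g(n)} (adequate for A much smaller than the
#' microwave quantum).  Lines carry Gaussian shapes whose width
#' interpolates the three principal-axis FWHM values, and the populations
#' enter through the thermal polarization of the doublet.
#'
#' @param doublet A [coupled_doublet()].
#' @param expt An [epr_experiment()].
#' @return A [spectrum_data()] of kind `"field"` (x in mT).  If no
#'   resonance falls in the swept range a warning is issued and the
#'   spectrum is zero.
#' @export
#' @examples
#' d <- coupled_doublet(g = 2.0023)
#' s <- simulate_powder_epr(d, epr_experiment(9.636, field_range_mT = c(300, 390)))
#' s$x[which.max(s$y)]   # low-field lobe of the derivative near 343.9 mT
simulate_powder_epr <- function(doublet, expt) {
  stopifnot(inherits(doublet, "coupled_doublet"),
            inherits(expt, "epr_experiment"))
  u <- .units
  gyro <- u$mu_B * u$MHz_per_cm1 / 1000      # MHz per mT per unit g
  grid <- powder_grid(expt$n_orientations, "octant")
  nvec <- rbind(grid$x, grid$y, grid$z)       # 3 x n, g-frame
  g <- doublet$g
  geff <- sqrt(colSums((g * nvec)^2))
  Amat <- rotate_tensor(doublet$A_Mn, doublet$euler_gA)
  AGn <- Amat %*% (g * nvec)
  aeff <- sqrt(colSums(AGn^2)) / geff         # MHz
  B0 <- expt$frequency_GHz * 1000 / (gyro * geff)   # mT
  dB <- aeff / (gyro * geff)                  # mT per m_I
  fwhm <- sqrt(colSums((expt$linewidth_mT * nvec)^2))
  # thermal polarization of the two doublet levels
  pol <- tanh(expt$frequency_GHz * 1000 / u$MHz_per_cm1 /
                (2 * u$k_B * expt$temperature_K))
  mI <- seq(-doublet$I_Mn, doublet$I_Mn)
  pos <- outer(dB, mI) + B0                   # n_orient x n_lines
  wts <- matrix(grid$w * pol / length(mI), nrow(pos), ncol(pos))
  x <- seq(expt$field_range_mT[1], expt$field_range_mT[2],
           length.out = expt$n_points)
  if (all(pos < x[1] - 4 * max(fwhm)) || all(pos > x[length(x)] + 4 * max(fwhm)))
    warning("no resonances fall inside the swept field range")
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(x))
  p <- as.vector(pos); w <- as.vector(wts); s <- rep(sd, ncol(pos))
  keep <- p > x[1] - 6 * max(sd) & p < x[length(x)] + 6 * max(sd)
  p <- p[keep]; w <- w[keep]; s <- s[keep]
  if (length(p)) {
    Z <- outer(x, p, "-") / rep(s, each = length(x))
    G <- exp(-Z^2 / 2) / (sqrt(2 * pi) * rep(s, each = length(x)))
    if (expt$derivative) G <- -Z / rep(s, each = length(x)) * G
    y <- as.numeric(G %*% w)
  }
  spectrum_data(x, y, kind = "field",
                meta = list(frequency_GHz = expt$frequency_GHz,
                            temperature_K = expt$temperature_K,
                            derivative = as.integer(expt$derivative)))
}

#' Effective g-values of the Kramers doublets of a half-integer spin
#'
#' Diagonalizes the zero-field-splitting Hamiltonian
#' \eqn{D[S_z^2 - S(S+1)/3] + E(S_x^2 - S_y^2)} (D > 0 by convention, so
#' the "lower" doublet of an S = 3/2 system is the mostly +/-1/2 pair) and
#' treats each zero-field Kramers doublet as a pseudo-spin 1/2: the
#' effective g along axis k is the first-order Zeeman splitting
#' \eqn{g_k^{eff} = g_{int} |\lambda_1 - \lambda_2|} of the 2x2 block of
#' S_k within the doublet.  This is the standard construction behind
#' rhombograms; for S = 3/2 with E/D = 0.16 it yields the observable
#' resonances near g = 5.8, 4.9 and 3.0.
#'
#' @param S Half-integer spin >= 3/2; integer spins are rejected
#'   (non-Kramers systems have no such doublet structure).
#' @param E_over_D Rhombicity, |E/D| <= 1/3.
#' @param g_int Intrinsic (isotropic) electronic g-value.
#' @return Matrix with one row per Kramers doublet (ordered by increasing
#'   zero-field energy) and columns `gx`, `gy`, `gz`; zero-field energies
#'   (units of D) attached as attribute `"energies"`.
#' @export
#' @examples
#' effective_g(3/2, 0)      # (4, 4, 2) and (0, 0, 6)
#' effective_g(3/2, 0.16)
effective_g <- function(S, E_over_D, g_int = 2) {
  if (abs(2 * S - round(2 * S)) > 1e-9 || S < 3/2)
    stop("S must be a half-integer >= 3/2, got ", format(S))
  if (abs(S - round(S)) < 1e-9)
    stop("integer S = ", S, " is non-Kramers; effective-g treatment ",
         "applies to half-integer spins only")
  if (abs(E_over_D) > 1/3 + 1e-12)
    stop("|E/D| must be <= 1/3, got ", format(E_over_D))
  sm <- spin_matrices(S)
  n <- nrow(sm$z)
  H <- (sm$z %*% sm$z - diag(S * (S + 1) / 3, n)) +
    E_over_D * (sm$x %*% sm$x - sm$y %*% sm$y)
  ev <- eigen(H, symmetric = TRUE)
  idx <- order(Re(ev$values))
  vals <- Re(ev$values)[idx]
  vecs <- ev$vectors[, idx, drop = FALSE]
  nd <- n %/% 2L
  out <- matrix(NA_real_, nd, 3L, dimnames = list(NULL, c("gx", "gy", "gz")))
  for (d in seq_len(nd)) {
    v <- vecs[, c(2 * d - 1, 2 * d)]
    for (k in 1:3) {
      Sk <- sm[[c("x", "y", "z")[k]]]
      M <- Conj(t(v)) %*% Sk %*% v
      lam <- eigen((M + Conj(t(M))) / 2, symmetric = TRUE,
                   only.values = TRUE)$values
      out[d, k] <- g_int * abs(lam[1] - lam[2])
    }
  }
  attr(out, "energies") <- vals[seq(1, n - 1, by = 2)]
  out
}
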