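# Spin operator algebra and tensor rotations.

#' Spin matrices for arbitrary half-integer spin
#'
#' Builds the three Cartesian angular-momentum matrices in the standard
#' |S, m> basis ordered m = S, S-1, ..., -S.  Sz is diagonal; Sx and Sy are
#' assembled from the ladder operators, so the matrices satisfy the
#' commutation relation \eqn{[S_x, S_y] = i S_z} exactly (to rounding).
#'
#' @param S Spin quantum number; 2S must be a non-negative integer.
#' @return List with complex matrices `x`, `y`, `z`, each (2S+1)-square.
#' @export
#' @examples
#' spin_matrices(1/2)$z            # diag(1/2, -1/2)
#' Re(diag(spin_matrices(2)$z))    # 2 1 0 -1 -2
spin_matrices <- function(S) {
  if (length(S) != 1L || !is.finite(S) || S < 0 ||
      abs(2 * S - round(2 * S)) > 1e-9)
    stop("S must be a non-negative half-integer, got ", format(S))
  m <- seq(S, -S, by = -1)
  n <- length(m)
  Sz <- diag(m, n, n) + 0i
  Sp <- matrix(0, n, n)
  if (n > 1L)
    for (i in 2:n) Sp[i - 1L, i] <- sqrt(S * (S + 1) - m[i] * (m[i] + 1))
  Sm <- t(Sp)
  list(x = (Sp + Sm) / 2 + 0i, y = (Sp - Sm) / (2i), z = Sz)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' The package uses the ZYZ convention throughout: `euler = c(alpha, beta,
#' gamma)` in degrees produces \eqn{R = R_z(\alpha) R_y(\beta) R_z(\gamma)}.
#' A tensor with principal values `p` in a frame rotated by these angles is
#' expressed in the reference frame as \eqn{R \, diag(p) \, R^T}.
#'
#' @param euler Three angles in degrees (angles wrap modulo 360).
#' @return 3x3 orthogonal matrix.
#' @export
euler_matrix <- function(euler) {
  stopifnot(length(euler) == 3L, all(is.finite(euler)))
  a <- euler * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a[1]) %*% ry(a[2]) %*% rz(a[3])
}

#' Express a tensor with given principal values in a rotated frame
#'
#' @param principal Three principal values.
#' @param euler ZYZ Euler angles in degrees rotating the tensor's principal
#'   frame relative to the reference frame (see [euler_matrix()]).
#' @return 3x3 symmetric matrix with eigenvalues `principal` and trace
#'   `sum(principal)`.
#' @export
#' @examples
#' rotate_tensor(c(1, 2, 3), c(0, 0, 0))   # diag(1, 2, 3)
rotate_tensor <- function(principal, euler = c(0, 0, 0)) {
  stopifnot(length(principal) == 3L, all(is.finite(principal)))
  R <- euler_matrix(euler)
  M <- R %*% diag(principal, 3, 3) %*% t(R)
  (M + t(M)) / 2
}
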