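# Structural descriptors of five-coordinate metal sites.

#' Trigonality index tau5 of a five-coordinate site
#'
#' \eqn{\tau_5 = (\beta - \alpha)/60} where beta and alpha are the largest
#' and second-largest ligand-metal-ligand angles.  1 for an ideal trigonal
#' bipyramid, 0 for an ideal square pyramid.  Invariant under permutation
#' of the angle list.
#'
#' @param angles Bond angles in degrees (at least 2).
#' @return Dimensionless tau5.
#' @export
#' @examples
#' tau5(c(177.85, 129.26, 120.53, 103.63))   # 0.810
tau5 <- function(angles) {
  if (length(angles) < 2L) stop("tau5 needs at least 2 bond angles")
  s <- sort(angles, decreasing = TRUE)
  (s[1] - s[2]) / 60
}

#' Displacement of a metal atom from a 3-atom ligand plane
#'
#' @param metal Metal position (3-vector, Angstrom).
#' @param plane_atoms 3x3 matrix (rows = the three plane atoms) or list of
#'   three 3-vectors; must be non-collinear.
#' @param axial Optional axial-ligand position; if given, the returned
#'   distance is signed positive towards it.
#' @return Point-to-plane distance in Angstrom (absolute unless `axial`
#'   is supplied).
#' @export
#' @examples
#' plane_displacement(c(0, 0, 0.3), rbind(c(1,0,0), c(0,1,0), c(-1,-1,0)))
plane_displacement <- function(metal, plane_atoms, axial = NULL) {
  if (is.list(plane_atoms)) plane_atoms <- do.call(rbind, plane_atoms)
  stopifnot(length(metal) == 3L, all(dim(plane_atoms) == c(3L, 3L)))
  v1 <- plane_atoms[2, ] - plane_atoms[1, ]
  v2 <- plane_atoms[3, ] - plane_atoms[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-10 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
    stop("plane atoms are collinear: no unique plane")
  nrm <- nrm / nn
  d <- sum((metal - plane_atoms[1, ]) * nrm)
  if (is.null(axial)) return(abs(d))
  s <- sign(sum((axial - plane_atoms[1, ]) * nrm))
  d * s
}

#' Ligand-metal-ligand bond angles from coordinates
#'
#' Convenience for computing the angle list consumed by [tau5()] directly
#' from atomic positions.
#'
#' @param metal Metal position (3-vector).
#' @param ligands Matrix (rows = ligand positions) or list of 3-vectors.
#' @return All pairwise L-M-L angles in degrees.
#' @export
coordination_angles <- function(metal, ligands) {
  if (is.list(ligands)) ligands <- do.call(rbind, ligands)
  n <- nrow(ligands)
  if (n < 2L) stop("need at least two ligand positions")
  vecs <- sweep(ligands, 2L, metal)
  vecs <- vecs / sqrt(rowSums(vecs^2))
  out <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    out <- c(out, acos(pmin(1, pmax(-1, sum(vecs[i, ] * vecs[j, ])))) *
               180 / pi)
  out
}
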