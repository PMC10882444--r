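# Deterministic powder-orientation grids.

#' Igloo orientation grid with solid-angle weights
#'
#' Deterministic triangular ("igloo") grid of field directions: rings of
#' constant polar angle with the azimuthal count proportional to
#' sin(theta), weighted by the solid angle each knot represents.  For
#' centrosymmetric interaction tensors one octant suffices; the full
#' hemisphere is available for problems that break octant symmetry.
#'
#' @param n Approximate number of orientations (>= 16).
#' @param region `"octant"` or `"hemisphere"`.
#' @return Data frame with unit-vector components `x`, `y`, `z` and
#'   normalized weights `w`.
#' @export
#' @examples
#' g <- powder_grid(100)
#' sum(g$w)   # 1
powder_grid <- function(n = 400, region = c("octant", "hemisphere")) {
  region <- match.arg(region)
  if (n < 16) stop("powder grid needs at least 16 orientations")
  phimax <- if (region == "octant") pi / 2 else 2 * pi
  nt <- max(4L, round(sqrt(n * pi / (4 * phimax) * 2)))
  dth <- (pi / 2) / nt
  th <- (seq_len(nt) - 0.5) * dth
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    np <- max(1L, round(phimax / dth * sin(th[k])))
    ph <- (seq_len(np) - 0.5) * phimax / np
    w <- sin(th[k]) * dth * (phimax / np)
    out[[k]] <- data.frame(x = sin(th[k]) * cos(ph), y = sin(th[k]) * sin(ph),
                           z = rep(cos(th[k]), np), w = rep(w, np))
  }
  g <- do.call(rbind, out)
  g$w <- g$w / sum(g$w)
  g
}
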