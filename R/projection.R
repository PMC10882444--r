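# Coupled <-> site representation algebra for exchange-coupled dimers.

#' Spin projection coefficients of a coupled multiplet
#'
#' For a total-spin multiplet S of a coupled pair (S1, S2), the site
#' operators project onto the coupled spin with coefficients
#' \deqn{c_i = \frac{S(S+1) + S_i(S_i+1) - S_j(S_j+1)}{2 S(S+1)},}
#' which satisfy c1 + c2 = 1.  For the S = 1/2 ground doublet of an
#' S1 = 5/2 / S2 = 2 pair these are (7/3, -4/3), the factors that map an
#' Fe(III)/Mn(III) pair's site tensors onto the coupled doublet.
#'
#' @param S1,S2 Site spins.
#' @param S_total Total spin; must satisfy the triangle rule
#'   |S1 - S2| <= S_total <= S1 + S2.
#' @return Named numeric vector `c(c1, c2)`.
#' @export
#' @examples
#' projection_coefficients(5/2, 2, 1/2)   #  7/3, -4/3
projection_coefficients <- function(S1, S2, S_total) {
  for (s in c(S1, S2, S_total))
    if (abs(2 * s - round(2 * s)) > 1e-9 || s < 0)
      stop("spins must be non-negative half-integers")
  if (S_total < abs(S1 - S2) - 1e-9 || S_total > S1 + S2 + 1e-9)
    stop("S_total = ", S_total, " violates the triangle rule |",
         S1, " - ", S2, "| <= S <= ", S1 + S2)
  if (S_total == 0)
    stop("S_total = 0 carries no Zeeman/hyperfine information to project")
  den <- 2 * S_total * (S_total + 1)
  c1 <- (S_total * (S_total + 1) + S1 * (S1 + 1) - S2 * (S2 + 1)) / den
  c(c1 = c1, c2 = 1 - c1)
}

#' g-values of a coupled multiplet from site g-values
#'
#' Componentwise projection g_c = c1 g1 + c2 g2.  With g_Fe = 2 and the
#' ground-doublet coefficients of a 5/2 x 2 pair this reduces to
#' g_c = 2 - (4/3)(g_Mn - 2), so site g-values below 2 appear above 2 in
#' the coupled doublet.
#'
#' @param g_site1,g_site2 Site g-values (3 components, scalars recycled).
#' @param coeffs Coefficients from [projection_coefficients()].
#' @return Three coupled g-values.
#' @export
#' @examples
#' coupled_g(2, 1.97, projection_coefficients(5/2, 2, 1/2))   # 2.04
coupled_g <- function(g_site1, g_site2, coeffs) {
  stopifnot(length(coeffs) == 2L)
  coeffs[1] * rep_len(g_site1, 3L) + coeffs[2] * rep_len(g_site2, 3L)
}

#' Map a fitted coupled hyperfine tensor back to the site
#'
#' EPR fitting of the coupled doublet yields only the magnitudes of the
#' coupled hyperfine components.  This maps them to the site through
#' A_site = A_coupled / c_site and fixes the overall sign by the stated
#' convention (the isotropic part of a Mn(III) 55Mn coupling is known to be
#' negative), then splits the result into the isotropic part
#' A_iso = trace/3 and the traceless spin-dipolar part A_SD.
#'
#' @param A_coupled Three coupled-representation magnitudes (MHz).
#' @param c_site Projection coefficient of the site (nonzero).
#' @param sign_convention `"negative_iso"` (default) or `"positive_iso"`.
#' @return List with `A_site` (signed, MHz), `A_iso`, `A_SD`, and the
#'   inputs, of class `site_projection`.
#' @export
#' @examples
#' p <- site_A_from_coupled(c(215, 243, 341), c_site = -4/3)
#' round(p$A_iso)   # -200
site_A_from_coupled <- function(A_coupled, c_site,
                                sign_convention = c("negative_iso",
                                                    "positive_iso")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(length(A_coupled) == 3L, all(is.finite(A_coupled)))
  if (!is.finite(c_site) || c_site == 0)
    stop("c_site = 0: this manifold carries no information about the site")
  A_site <- abs(A_coupled) / abs(c_site)
  want <- if (sign_convention == "negative_iso") -1 else 1
  A_site <- want * A_site
  A_iso <- mean(A_site)
  structure(list(A_site = A_site, A_iso = A_iso, A_SD = A_site - A_iso,
                 A_coupled = A_coupled, c_site = c_site,
                 sign_convention = sign_convention),
            class = "site_projection")
}

#' @export
print.site_projection <- function(x, ...) {
  cat("<site_projection>\n")
  cat("  A_coupled (MHz):", paste(format(x$A_coupled), collapse = ", "), "\n")
  cat("  c_site         :", format(x$c_site), "\n")
  cat("  A_site    (MHz):", paste(format(round(x$A_site, 2)), collapse = ", "), "\n")
  cat("  A_iso     (MHz):", format(round(x$A_iso, 2)),
      " ->", round(x$A_iso), "(rounded)\n")
  cat("  A_SD      (MHz):", paste(format(round(x$A_SD, 2)), collapse = ", "), "\n")
  invisible(x)
}
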