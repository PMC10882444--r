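# Seeded synthetic-data generators: every experiment the package can fit
# can also be generated from declared ground truth, so all recovery tests
# run without experimental downloads.  Noise is additive Gaussian on the
# ordinate with standard deviation given relative to the peak amplitude;
# the same truth and seed always produce identical data.

.add_noise <- function(y, noise_sd, seed) {
  if (noise_sd <= 0) return(y)
  set.seed(as.integer(seed %% .Machine$integer.max))
  y + stats::rnorm(length(y), 0, noise_sd * max(abs(y)))
}

#' Generate a two-frequency EPR dataset from declared truth
#'
#' Simulates the S- and X-band powder spectra of a coupled doublet and
#' adds seeded Gaussian noise.  A truth sidecar recording all generating
#' parameters accompanies the data so tests never re-derive ground truth.
#'
#' @param doublet A [coupled_doublet()] (the ground truth).
#' @param frequencies_GHz Microwave frequencies (default the two-band pair
#'   3.485 and 9.636 GHz).
#' @param noise_sd Gaussian noise, relative to the peak amplitude.
#' @param seed Integer seed.
#' @param linewidth_mT,field_range_mT,n_points,n_orientations Passed to
#'   [epr_experiment()].
#' @param out_dir If non-NULL, write `epr_<freq>GHz.dat` spectrum files
#'   and `truth.cfg` there.
#' @return List with `spectra` (list of [spectrum_data()]) and `truth`.
#' @export
generate_epr_dataset <- function(doublet, frequencies_GHz = c(3.485, 9.636),
                                 noise_sd = 0.02, seed = 1,
                                 linewidth_mT = 3,
                                 field_range_mT = NULL, n_points = 1024,
                                 n_orientations = 200, out_dir = NULL) {
  stopifnot(inherits(doublet, "coupled_doublet"))
  spectra <- lapply(seq_along(frequencies_GHz), function(i) {
    f <- frequencies_GHz[i]
    rng <- if (is.null(field_range_mT)) {
      B0 <- f * 1000 / (.units$mu_B * .units$MHz_per_cm1 / 1000 *
                          mean(doublet$g))
      c(B0 - 60, B0 + 60)
    } else field_range_mT
    ex <- epr_experiment(f, field_range_mT = rng, n_points = n_points,
                         linewidth_mT = linewidth_mT,
                         n_orientations = n_orientations)
    s <- simulate_powder_epr(doublet, ex)
    s$y <- .add_noise(s$y, noise_sd, seed + i)
    s
  })
  truth <- list(g = doublet$g, A_Mn = doublet$A_Mn,
                euler_gA = doublet$euler_gA, I_Mn = doublet$I_Mn,
                linewidth_mT = linewidth_mT, noise_sd = noise_sd,
                seed = seed, frequencies_GHz = frequencies_GHz)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(spectra))
      write_spectrum(spectra[[i]], file.path(out_dir,
        sprintf("epr_%.3fGHz.dat", frequencies_GHz[i])))
    write_config(list(truth = truth), file.path(out_dir, "truth.cfg"))
  }
  list(spectra = spectra, truth = truth)
}

#' Generate a temperature-dependence series from an exchange ladder
#'
#' @param J,S1,S2,S_target Ladder truth passed to [signal_t_product()].
#' @param temperatures Measurement temperatures (K).
#' @param scale Overall intensity scale.
#' @param noise_sd Relative Gaussian noise.
#' @param seed Integer seed.
#' @param out_dir If non-NULL, write `tempdep.dat` and `truth.cfg`.
#' @return List with `series` (data frame `T`, `value`) and `truth`.
#' @export
generate_tempdep_dataset <- function(J = 40, S1 = 5/2, S2 = 2,
                                     S_target = 3/2,
                                     temperatures = seq(8, 60,
                                                        length.out = 8),
                                     scale = 1, noise_sd = 0.05, seed = 1,
                                     out_dir = NULL) {
  y <- scale * signal_t_product(J, S1, S2, S_target, temperatures)
  y <- .add_noise(y, noise_sd, seed)
  series <- data.frame(T = temperatures, value = y)
  truth <- list(J = J, S1 = S1, S2 = S2, S_target = S_target, scale = scale,
                noise_sd = noise_sd, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series(series, file.path(out_dir, "tempdep.dat"),
                 meta = list(kind = "temperature"))
    write_config(list(truth = truth), file.path(out_dir, "truth.cfg"))
  }
  list(series = series, truth = truth)
}

#' Generate a power-saturation (P1/2) series from an Orbach model
#'
#' @param Delta Orbach gap (cm^-1); for a 5/2 x 2 ladder Delta = 3J/2.
#' @param a,b Direct-process slope and Orbach prefactor.
#' @param temperatures Measurement temperatures (K).
#' @param noise_sd Relative Gaussian noise (applied on the log scale so
#'   every decade is perturbed comparably).
#' @param seed Integer seed.
#' @param out_dir If non-NULL, write `psat.dat` and `truth.cfg`.
#' @return List with `series` (data frame `T`, `p_half`) and `truth`.
#' @export
generate_psat_dataset <- function(Delta = 180, a = 0.05, b = 5e4,
                                  temperatures = c(4, 6, 8, 11, 15, 20,
                                                   27, 35),
                                  noise_sd = 0.1, seed = 1, out_dir = NULL) {
  mu <- a * temperatures + b / expm1(Delta / (.units$k_B * temperatures))
  if (noise_sd > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    mu <- mu * exp(stats::rnorm(length(mu), 0, noise_sd))
  }
  series <- data.frame(T = temperatures, p_half = mu)
  truth <- list(Delta = Delta, a = a, b = b, noise_sd = noise_sd, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(T = series$T, value = series$p_half)
    write_series(df, file.path(out_dir, "psat.dat"))
    write_config(list(truth = truth), file.path(out_dir, "truth.cfg"))
  }
  list(series = series, truth = truth)
}

#' Generate multi-field Moessbauer spectra from declared truth
#'
#' Simulates 4.2 K spectra of one species (or a two-species mixture) at
#' the requested applied fields and adds seeded Gaussian noise.
#'
#' @param site A [mossbauer_site()] truth for the main species.
#' @param dimer An [exchange_dimer()] for the main species.
#' @param expt A [mossbauer_experiment()] (fields, geometry, grids).
#' @param components Optional mixture specification as in
#'   [simulate_mossbauer()]; overrides `site`/`dimer`.
#' @param electronic Electronic model, as in [simulate_mossbauer()].
#' @param noise_sd Relative Gaussian noise.
#' @param seed Integer seed.
#' @param out_dir If non-NULL, write `moss_<field>T.dat` files and
#'   `truth.cfg`.
#' @return List with `spectra` and `truth`.
#' @export
generate_mossbauer_dataset <- function(site, dimer, expt, components = NULL,
                                       electronic = "full", noise_sd = 0.01,
                                       seed = 1, out_dir = NULL) {
  spectra <- simulate_mossbauer(site, dimer, expt, electronic = electronic,
                                components = components)
  for (i in seq_along(spectra))
    spectra[[i]]$y <- .add_noise(spectra[[i]]$y, noise_sd, seed + i)
  truth <- list(delta = site$delta, dEQ = site$dEQ, eta = site$eta,
                A_Fe = site$A_Fe, gamma = site$gamma, J = dimer$J,
                fields_T = expt$fields_T, include_mn = expt$include_mn,
                noise_sd = noise_sd, seed = seed,
                fractions = if (!is.null(components))
                  vapply(components, `[[`, 0, "fraction") else 1)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(spectra))
      write_spectrum(spectra[[i]], file.path(out_dir,
        sprintf("moss_%gT.dat", expt$fields_T[i])))
    write_config(list(truth = truth[!vapply(truth, is.null, TRUE)]),
                 file.path(out_dir, "truth.cfg"))
  }
  list(spectra = spectra, truth = truth)
}
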