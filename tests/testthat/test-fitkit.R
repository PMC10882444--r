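# Shared least-squares engine: multi-frequency EPR fits and profiles.

# Spectra simulated from a fitted parameter set must reproduce the data;
# g/A tensors are compared up to the axis-permutation symmetry of the
# powder problem (relabelling principal axes with the matching Euler
# rotation leaves every spectrum invariant).
fitted_doublet <- function(fit) {
  coupled_doublet(g = fit$par[c("g1", "g2", "g3")],
                  A_Mn = fit$par[c("A1", "A2", "A3")],
                  euler_gA = fit$par[c("alpha", "beta", "gamma_e")])
}

test_that("noiseless two-frequency data are recovered exactly", {
  dbl <- make_doublet(doublet_rows$oxo)
  gen <- generate_epr_dataset(dbl, noise_sd = 0, n_points = 512,
                              n_orientations = 150)
  guess <- coupled_doublet(g = c(2.04, 2.03, 2.01),
                           A_Mn = c(220, 240, 330), euler_gA = c(70, 50, 80))
  fit <- fit_epr_multifrequency(gen$spectra, guess, n_starts = 1,
                                n_orientations = 150)
  expect_true(fit$converged)
  # residual essentially zero: the fitted set reproduces both bands
  expect_lt(fit$residual_norm, 1e-6)
  expect_equal(sort(unname(fit$par[c("g1", "g2", "g3")])),
               sort(doublet_rows$oxo$g), tolerance = 1e-5)
  expect_equal(sort(unname(fit$par[c("A1", "A2", "A3")])),
               sort(doublet_rows$oxo$A), tolerance = 1e-4)
  # simulating from the fit reproduces the data on both bands
  for (i in 1:2) {
    ex <- epr_experiment(as.numeric(gen$spectra[[i]]$meta$frequency_GHz),
                         field_range_mT = range(gen$spectra[[i]]$x),
                         n_points = length(gen$spectra[[i]]$x),
                         linewidth_mT = unname(fit$par["lw"]),
                         n_orientations = 150)
    yh <- simulate_powder_epr(fitted_doublet(fit), ex)$y
    expect_lt(max(abs(yh / max(abs(yh)) -
                        gen$spectra[[i]]$y / max(abs(gen$spectra[[i]]$y)))),
              1e-5)
  }
})

test_that("2% noise leaves g within 0.002 and A within 5 MHz", {
  dbl <- make_doublet(doublet_rows$oxo)
  gen <- generate_epr_dataset(dbl, noise_sd = 0.02, seed = 5, n_points = 512,
                              n_orientations = 150)
  guess <- coupled_doublet(g = c(2.04, 2.03, 2.01),
                           A_Mn = c(220, 240, 330), euler_gA = c(70, 50, 80))
  fit <- fit_epr_multifrequency(gen$spectra, guess, n_starts = 1,
                                n_orientations = 150)
  expect_lt(max(abs(sort(unname(fit$par[c("g1", "g2", "g3")])) -
                      sort(doublet_rows$oxo$g))), 0.002)
  expect_lt(max(abs(sort(unname(fit$par[c("A1", "A2", "A3")])) -
                      sort(doublet_rows$oxo$A))), 5)
})

test_that("forcing the g/A rotation to zero worsens the simultaneous fit", {
  dbl <- make_doublet(doublet_rows$oxo)
  gen <- generate_epr_dataset(dbl, noise_sd = 0, n_points = 512,
                              n_orientations = 150)
  guess0 <- coupled_doublet(g = doublet_rows$oxo$g,
                            A_Mn = doublet_rows$oxo$A,
                            euler_gA = c(0, 0, 0))
  fit_free <- fit_epr_multifrequency(gen$spectra,
                                     make_doublet(doublet_rows$oxo),
                                     n_starts = 1, n_orientations = 150)
  fit_const <- fit_epr_multifrequency(gen$spectra, guess0,
                                      float_euler = FALSE, n_starts = 1,
                                      n_orientations = 150)
  expect_gt(fit_const$residual_norm, 10 * fit_free$residual_norm)
})

test_that("missing frequency metadata is rejected", {
  s <- spectrum_data(1:10, rnorm(10), kind = "field")
  expect_error(fit_epr_multifrequency(list(s, s),
                                      coupled_doublet(g = 2)),
               "frequency_GHz")
})

test_that("fits are deterministic given data, guess and seed", {
  gen <- generate_tempdep_dataset(J = 40, noise_sd = 0.05, seed = 2)
  f1 <- fit_exchange_tempdep(gen$series)
  f2 <- fit_exchange_tempdep(gen$series)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$residual_norm, f2$residual_norm)
})

test_that("residual profiles are quadratic near a well-identified minimum", {
  gen <- generate_tempdep_dataset(J = 40, noise_sd = 0.03, seed = 9)
  fit <- fit_exchange_tempdep(gen$series)
  grid <- seq(30, 50, by = 1)
  prof <- profile_uncertainty(fit, "J", grid)
  expect_true(attr(prof, "identifiable"))
  jmin <- prof$value[which.min(prof$residual_norm)]
  expect_lt(abs(jmin - fit$par["J"]), 1.0)
  # monotone on both sides of the minimum
  i <- which.min(prof$residual_norm)
  expect_true(all(diff(prof$residual_norm[1:i]) <= 0))
  expect_true(all(diff(prof$residual_norm[i:length(grid)]) >= 0))
})

test_that("flat profiles raise the non-identifiability flag", {
  fit <- fit_result(par = c(a = 1, b = 2), se = c(a = 0.1, b = NA),
                    residual_norm = 1, n_eval = 1, converged = TRUE,
                    objective = function(p) c(p["a"] - 1, p["a"] + 1))
  expect_warning(prof <- profile_uncertainty(fit, "b", seq(0, 4, 0.5)),
                 "non-identifiable")
  expect_false(attr(prof, "identifiable"))
})

test_that("reported estimates reproduce the residual norm", {
  gen <- generate_tempdep_dataset(J = 40, noise_sd = 0.05, seed = 2)
  fit <- fit_exchange_tempdep(gen$series)
  expect_equal(sqrt(sum(fit$objective(fit$par)^2)), fit$residual_norm,
               tolerance = 1e-8)
})
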