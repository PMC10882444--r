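# Variable-field 57Fe Moessbauer simulation and fitting.

moss_expt <- function(fields, norient = 40, npts = 512, rng = c(-12, 12),
                      ...)
  mossbauer_experiment(fields_T = fields, n_orientations = norient,
                       n_points = npts, velocity_range = rng, ...)

# local maxima with sub-grid parabolic refinement
peak_positions <- function(s) {
  i <- which(diff(sign(diff(s$y))) == -2) + 1
  dx <- s$x[2] - s$x[1]
  s$x[i] + dx * 0.5 * (s$y[i - 1] - s$y[i + 1]) /
    (s$y[i - 1] - 2 * s$y[i] + s$y[i + 1])
}

test_that("zero-field quadrupole doublet has the textbook geometry", {
  st <- mossbauer_site(delta = 0.53, dEQ = -1.84, A_Fe = 0, gamma = 0.25)
  dm <- make_femn_dimer(with_mn = FALSE)
  sp <- simulate_mossbauer(st, dm, moss_expt(0, norient = 20, npts = 1024,
                                             rng = c(-4, 5)))[[1]]
  pk <- peak_positions(sp)
  expect_length(pk, 2L)
  expect_equal(abs(diff(pk)), 1.84, tolerance = 3e-3)
  expect_equal(mean(pk), 0.53, tolerance = 3e-3)
  # the two lines are equally intense in a powder
  h <- sp$y[which(diff(sign(diff(sp$y))) == -2) + 1]
  expect_equal(h[1] / h[2], 1, tolerance = 0.02)
})

test_that("magnetic hyperfine limits give the standard intensity ratios", {
  # line-level check of the angular machinery: a large internal field with
  # randomly oriented B_eff (isotropic <cos^2> = 1/3) gives the powder
  # sextet 3:2:1:1:2:3
  st <- mossbauer_site(delta = 0, dEQ = 0, A_Fe = -20, gamma = 0.2)
  ln <- dimerspec:::.fe_lines(st, Beff = c(0, 0, 20), c2 = 1/3)
  keep <- ln[ln[, "int"] > 1e-12, ]
  keep <- keep[order(keep[, "v"]), ]
  expect_equal(nrow(keep), 6L)
  expect_equal(keep[, "int"] / min(keep[, "int"]), c(3, 2, 1, 1, 2, 3),
               tolerance = 1e-9)
  # field parallel to the beam: Delta-m = 0 lines vanish (3:0:1 pattern)
  lnp <- dimerspec:::.fe_lines(st, Beff = c(0, 0, 20), c2 = 1)
  keep_p <- lnp[lnp[, "int"] > 1e-12, ]
  expect_equal(nrow(keep_p), 4L)
  # field perpendicular to the beam: 3:4:1
  lnt <- dimerspec:::.fe_lines(st, Beff = c(0, 0, 20), c2 = 0)
  keep_t <- lnt[lnt[, "int"] > 1e-12, ]
  keep_t <- keep_t[order(keep_t[, "v"]), ]
  expect_equal(keep_t[, "int"] / min(keep_t[, "int"]), c(3, 4, 1, 1, 4, 3),
               tolerance = 1e-9)
})

test_that("iron-site spin expectations follow the projection theorem", {
  dm <- make_femn_dimer(J = 120)
  se <- spin_expectation_fe(dm, B = 4, temperature = 4.2)
  expect_equal(sort(se$Sz), c(-7/6, 7/6), tolerance = 1e-3)
  # B = 0: Kramers partners carry opposite expectations, net zero
  se0 <- spin_expectation_fe(dm, B = 0, temperature = 4.2)
  expect_equal(sum(se0$weight * se0$Sz), 0, tolerance = 1e-8)
  expect_equal(sum(se0$weight), 1)
})

test_that("the 55Mn nuclear spin broadens <S_Fe> at low field only", {
  dm <- make_femn_dimer(J = 120)
  spread <- function(B) {
    se <- spin_expectation_fe(dm, B = c(0, 0, B), temperature = 4.2,
                              include_mn_nucleus = TRUE)
    # spread of |<S_Fe,z>| across the electron-nuclear levels of the
    # lower electronic branch
    lower <- se[se$Sz < 0, ]
    diff(range(lower$Sz))
  }
  expect_gt(spread(0.045), 0.05)     # a sizeable fraction of 1/2
  expect_lt(spread(4), 1e-3)
})

test_that("absorption area is conserved across applied fields", {
  st <- make_moss_site()
  dm <- make_femn_dimer(J = 120, with_mn = FALSE)
  areas <- vapply(simulate_mossbauer(st, dm, moss_expt(c(0.045, 0.5, 4))),
                  function(s) sum(s$y) * diff(s$x[1:2]), 0)
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
})

test_that("including the 55Mn nucleus changes only the low-field spectra", {
  st <- make_moss_site()
  dm <- make_femn_dimer(J = 120)
  rms <- vapply(c(0.0075, 0.045, 4), function(B) {
    ex <- moss_expt(B)
    a <- simulate_mossbauer(st, dm, ex)[[1]]$y
    ex$include_mn <- TRUE
    b <- simulate_mossbauer(st, dm, ex)[[1]]$y
    sqrt(mean((a - b)^2)) / max(a)
  }, 0)
  expect_gt(rms[1], 0.05)
  expect_gt(rms[2], 0.05)
  expect_lt(rms[3], 0.01)
})

test_that("55Mn inclusion reduces the apparent line splitting at 45 mT", {
  # second moment of the absorption about its centroid shrinks when the
  # Mn nucleus shares the electronic polarization
  st <- make_moss_site()
  dm <- make_femn_dimer(J = 120)
  ex <- moss_expt(0.045)
  mom2 <- function(s) {
    w <- s$y / sum(s$y)
    m <- sum(w * s$x)
    sum(w * (s$x - m)^2)
  }
  a <- simulate_mossbauer(st, dm, ex)[[1]]
  ex$include_mn <- TRUE
  b <- simulate_mossbauer(st, dm, ex)[[1]]
  expect_lt(mom2(b), mom2(a))
})

test_that("projected-doublet model matches the full matrix in strong exchange", {
  st <- make_moss_site()
  dm <- make_femn_dimer(J = 120)
  for (B in c(0.045, 4)) {
    ex <- moss_expt(B, norient = 30)
    a <- simulate_mossbauer(st, dm, ex, electronic = "full")[[1]]$y
    b <- simulate_mossbauer(st, dm, ex, electronic = "doublet")[[1]]$y
    expect_lt(sqrt(mean((a - b)^2)) / max(a), 0.02)
  }
})

test_that("multi-field fitting recovers the site parameters", {
  dm <- make_femn_dimer(J = 120, with_mn = FALSE)
  truth <- make_moss_site()
  ex <- moss_expt(c(0.045, 4), norient = 60, npts = 400, rng = c(-11, 11))
  gen <- generate_mossbauer_dataset(truth, dm, ex, noise_sd = 0.01, seed = 7)
  guess <- mossbauer_site(delta = 0.4, dEQ = -1.5, A_Fe = -17, gamma = 0.3)
  fit <- fit_mossbauer(gen$spectra, dm, guess,
                       float = c("delta", "dEQ", "A_iso"),
                       n_orientations = 60)
  expect_true(fit$converged)
  expect_lt(abs(fit$par["delta"] - 0.53), 2 * fit$se["delta"])
  expect_lt(abs(fit$par["dEQ"] - (-1.84)), 2 * fit$se["dEQ"])
  expect_lt(abs(fit$par["A_iso"] - (-20)), 2 * fit$se["A_iso"])
  # and all three land well inside spectroscopically meaningful bounds
  expect_lt(abs(fit$par["delta"] - 0.53), 0.02)
  expect_lt(abs(fit$par["dEQ"] - (-1.84)), 0.05)
  expect_lt(abs(fit$par["A_iso"] - (-20)), 0.5)
})

test_that("a minor species fraction is recovered from a mixture", {
  # Fe(III)Mn(IV) main species contaminated by 15% of the Fe(III)Mn(III)
  # complex, as seen in the oxidized samples
  dm_main <- exchange_dimer(spin_site("Fe", 5/2), spin_site("Mn", 3/2),
                            J = 150)
  st_main <- mossbauer_site(delta = 0.50, dEQ = -1.31, A_Fe = -20,
                            gamma = 0.3)
  dm_min <- make_femn_dimer(J = 120, with_mn = FALSE)
  st_min <- make_moss_site()
  ex <- moss_expt(c(0.045, 4), norient = 40, npts = 300, rng = c(-11, 11))
  gen <- generate_mossbauer_dataset(
    st_main, dm_main, ex, noise_sd = 0.01, seed = 21,
    components = list(list(site = st_main, dimer = dm_main, fraction = 0.85),
                      list(site = st_min, dimer = dm_min, fraction = 0.15)))
  guess <- mossbauer_site(delta = 0.45, dEQ = -1.2, A_Fe = -19, gamma = 0.3)
  fit <- fit_mossbauer(gen$spectra, dm_main, guess,
                       float = c("delta", "dEQ", "A_iso", "fraction"),
                       minor = list(site = st_min, dimer = dm_min),
                       fraction = 0.10, n_orientations = 40)
  expect_lt(abs(fit$par["fraction"] - 0.15), 0.03)
  expect_lt(abs(fit$par["delta"] - 0.50), 0.02)
})

test_that("zero-field data leave the sign of dEQ undetermined", {
  dm <- make_femn_dimer(with_mn = FALSE)
  truth <- mossbauer_site(delta = 0.53, dEQ = -1.84, A_Fe = 0, gamma = 0.25)
  ex <- moss_expt(0, norient = 16, npts = 400, rng = c(-4, 5))
  gen <- generate_mossbauer_dataset(truth, dm, ex, noise_sd = 0, seed = 1)
  guess <- mossbauer_site(delta = 0.4, dEQ = +1.6, A_Fe = 0, gamma = 0.25)
  expect_warning(
    fit <- fit_mossbauer(gen$spectra, dm, guess, float = c("delta", "dEQ"),
                         n_orientations = 16),
    "sign of dEQ")
  expect_equal(unname(fit$par["delta"]), 0.53, tolerance = 1e-3)
  expect_equal(abs(unname(fit$par["dEQ"])), 1.84, tolerance = 1e-3)
})
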