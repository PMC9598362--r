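pbs <- solution_spec("1xPBS", 0.2853)
table2 <- avrami_params(0.53, 3.3, 1.5, pbs$Tph)

test_that("release-curve generator passes the forward model through and is
           seed-deterministic", {
  # equilibrium model, no noise: identical to the lever rule
  sp <- synth_spec(pbs, cooling_rate = 1)
  cv <- generate_release_curves(sp)[[1]]
  expect_equal(cv$fraction,
               equilibrium_release_fraction(cv$temperature, pbs),
               tolerance = 1e-12)
  # kinetic lag: 20 K/min curve below the 1 K/min curve below Tph
  f20 <- generate_release_curves(synth_spec(pbs, 20, model = table2))[[1]]
  f1 <- generate_release_curves(synth_spec(pbs, 1, model = table2))[[1]]
  expect_true(all(f20$fraction[-1] < f1$fraction[-1]))
  # determinism contract
  mk <- function(seed) generate_release_curves(
    synth_spec(pbs, 5, model = table2, noise_fraction = 0.01,
               replicates = 3, seed = seed))
  a <- mk(4); b <- mk(4); c <- mk(5)
  expect_identical(lapply(a, `[[`, "fraction"), lapply(b, `[[`, "fraction"))
  expect_false(identical(a[[1]]$fraction, c[[1]]$fraction))
  expect_length(a, 3)
  expect_true(all(vapply(a, function(cv)
    all(cv$fraction >= 0 & cv$fraction <= 1), logical(1))))
  expect_error(synth_spec(pbs, 5, noise_fraction = 0.01), "seed")
})

test_that("release-curve CSV and sidecar survive a write/read round trip", {
  sp <- synth_spec(pbs, 5, model = table2, noise_fraction = 0.005,
                   replicates = 2, seed = 9)
  curves <- generate_release_curves(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_release_curves(curves, path)
  back <- read_release_curves(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$fraction, curves[[1]]$fraction, tolerance = 1e-9)
  expect_identical(attr(back[[2]], "cooling_rate"), 5)
  expect_equal(attr(back[[1]], "solution")$osmolality, 0.2853)
})

test_that("synthetic thermograms carry the configured enthalpy and a
           detectable nucleation spike", {
  sp <- synth_spec(pbs, 5, model = table2, nucleation_temp = -9.5, seed = 2)
  tg <- generate_thermogram(sp)
  hit <- detect_nucleation(tg)
  expect_equal(hit$temperature_C, -9.5, tolerance = 0.2)
  il <- integrate_latent_heat(tg, linear_baseline(tg))
  # the saline exotherm tail extends past the -40 degC anchor, so the
  # windowed integral sits ~1% below the configured total
  expect_equal(il$latent_heat_mJ_mg, 335, tolerance = 0.015)
  # randomly drawn nucleation temperature stays in the protocol window
  tg2 <- generate_thermogram(synth_spec(pbs, 5, model = table2, seed = 3,
                                        noise_mW = 0.01))
  hit2 <- detect_nucleation(tg2)
  expect_true(hit2$temperature_C >= -12.5 && hit2$temperature_C <= -5.5)
  # under-sampled transition is refused
  expect_error(generate_thermogram(synth_spec(pbs, 20, model = table2,
                                              sampling_hz = 0.05)),
               "sampling rate too low")
})

test_that("full pipeline recovers the generating parameters through both
           data paths", {
  # release-curve path: exact at zero noise
  curves <- c(generate_release_curves(synth_spec(pbs, 5, model = table2)),
              generate_release_curves(synth_spec(pbs, 20, model = table2)))
  slow <- generate_release_curves(synth_spec(pbs, 1, model = table2))[[1]]
  fitA <- fit_temperature_constant(slow, Tph = pbs$Tph)
  fit <- fit_kinetics(curves, A = 0.53, Tph = pbs$Tph)
  expect_equal(fit$k, 3.3, tolerance = 1e-6)
  expect_equal(fit$n, 1.5, tolerance = 1e-6)
  # thermogram path: window normalisation biases the refit k by ~10%
  tgs <- lapply(c(1, 5, 20), function(B)
    generate_thermogram(synth_spec(pbs, B, model = table2,
                                   nucleation_temp = -8)))
  cvs <- lapply(tgs, function(tg)
    cumulative_release_curve(tg, linear_baseline(tg)))
  fitA2 <- fit_temperature_constant(cvs[[1]], Tph = pbs$Tph)
  fit2 <- fit_kinetics(cvs[2:3], A = fitA2$A, Tph = pbs$Tph)
  expect_equal(fitA2$A, 0.53, tolerance = 0.02)
  expect_equal(fit2$k, 3.3, tolerance = 0.15)
  expect_equal(fit2$n, 1.5, tolerance = 0.05)
})

test_that("fitted-parameter error grows with the noise level", {
  rmse_k <- vapply(c(0.005, 0.02, 0.08), function(sig) {
    errs <- vapply(1:8, function(i) {
      curves <- c(
        generate_release_curves(synth_spec(pbs, 5, model = table2,
                                           noise_fraction = sig,
                                           n_points = 40,
                                           seed = 100 * i + sig * 1000)),
        generate_release_curves(synth_spec(pbs, 20, model = table2,
                                           noise_fraction = sig,
                                           n_points = 40,
                                           seed = 200 * i + sig * 1000)))
      fit_kinetics(curves, A = 0.53, Tph = pbs$Tph)$k - 3.3
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse_k) > 0))
})

test_that("a stefan-model generator produces a usable lagged curve", {
  sp <- synth_spec(pbs, 5, model = stefan_params(cooling_rate = 5),
                   n_points = 60)
  cv <- generate_release_curves(sp)[[1]]
  expect_identical(cv$fraction[1], 0)
  expect_equal(cv$fraction[nrow(cv)], 1, tolerance = 1e-6)
  expect_true(all(diff(cv$fraction) >= -1e-12))
})
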