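# simple constant-rate fixture: ramp from T0 at `rate` K/min, flat or
# user-supplied heat flow, 1 Hz sampling
ramp_tg <- function(heat_flow, T0 = 0, rate = 5, mass = 10, n = length(heat_flow)) {
  tt <- seq(0, n - 1)
  thermogram(tt, T0 - rate / 60 * tt, heat_flow, sample_mass_mg = mass,
             cooling_rate = rate)
}

test_that("thermogram CSV round trip is lossless and units auto-convert", {
  tg <- thermogram(c(0, 0.1, 0.2), c(4, 3.99, 3.98),
                   c(0.51234567890123, 0.5, 0.49),
                   sample_mass_mg = 9.5, cooling_rate = 5,
                   solution = solution_spec("1xPBS", 0.2853))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram(tg, path)
  back <- read_thermogram(path)
  expect_identical(nrow(back), 3L)
  expect_identical(back$heat_flow_mW, tg$heat_flow_mW)
  expect_identical(back$time_s, tg$time_s)
  expect_identical(attr(back, "sample_mass_mg"), 9.5)
  expect_equal(attr(back, "solution")$Tph, 272.62, tolerance = 1e-4)
  # kelvin temperature column converted on read
  pk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_mass_mg: 10", "# cooling_rate_K_min: 5",
               "time_s,temperature_K,heat_flow_mW",
               "0,277.15,0.5", "1,277.05,0.5", "2,276.95,0.5"), pk)
  expect_equal(read_thermogram(pk)$temperature_C, c(4, 3.9, 3.8),
               tolerance = 1e-12)
})

test_that("thermogram parsing rejects malformed files with specific errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_mass_mg: 10", "# cooling_rate_K_min: 5",
               "time_s,temperature_C", "0,4", "1,3.9"), path)
  expect_error(read_thermogram(path), "heat_flow_mW")
  writeLines(c("# sample_mass_mg: 10", "# cooling_rate_K_min: 5",
               "time_s,temperature_C,heat_flow_mW", "1,4,0.5", "0,3.9,0.5"),
             path)
  expect_error(read_thermogram(path), "non-monotone")
  writeLines(c("# cooling_rate_K_min: 5",
               "time_s,temperature_C,heat_flow_mW", "0,4,0.5", "1,3.9,0.5"),
             path)
  expect_error(read_thermogram(path), "sample_mass_mg")
})

test_that("nucleation detector finds the spike, honours prominence and
           breaks ties toward the warmer sample", {
  n <- 200
  base <- rep(0.2, n)
  spike_at <- function(T_target, amp, sig = base) {
    tg0 <- ramp_tg(sig, T0 = 0)
    i <- which.min(abs(tg0$temperature_C - T_target))
    sig[(i - 2):(i + 2)] <- sig[(i - 2):(i + 2)] - amp * c(.3, .7, 1, .7, .3)
    list(tg = ramp_tg(sig, T0 = 0), i = i)
  }
  one <- spike_at(-8, 5)
  hit <- detect_nucleation(one$tg, median_k = 21)
  expect_lte(abs(hit$index - one$i), 1)
  expect_equal(hit$temperature_C, -8, tolerance = 0.1)
  # flat signal: nothing to find
  expect_message(res <- detect_nucleation(ramp_tg(base), median_k = 21),
                 "no nucleation")
  expect_null(res)
  # two spikes: the more prominent one wins
  two <- spike_at(-10.5, 8, sig = spike_at(-7.5, 4)$tg$heat_flow_mW)
  expect_equal(detect_nucleation(two$tg, median_k = 21)$temperature_C,
               -10.5, tolerance = 0.1)
  # exact tie between identical spikes: the earlier (warmer) sample wins
  tie <- spike_at(-9.5, 5, sig = spike_at(-8.5, 5)$tg$heat_flow_mW)
  expect_equal(detect_nucleation(tie$tg, median_k = 21)$temperature_C,
               -8.5, tolerance = 0.1)
})

test_that("linear baseline matches the signal chord between the anchors", {
  # signal already linear between anchors: baseline == signal, integral 0
  n <- 400
  sig <- 0.3 + 0.001 * seq(0, n - 1)
  tg <- ramp_tg(sig)
  bl <- linear_baseline(tg, T_start = -1, T_end = -25)
  expect_equal(bl$values, sig[bl$index], tolerance = 1e-12)
  expect_equal(integrate_latent_heat(tg, bl)$latent_heat_mJ_mg, 0,
               tolerance = 1e-12)
  # equal anchor values give a horizontal baseline
  sym <- rep(0.5, n); sym[150:250] <- 0.5 - 3
  tg2 <- ramp_tg(sym)
  bl2 <- linear_baseline(tg2, T_start = -1, T_end = -25)
  expect_true(all(bl2$values == 0.5))
  expect_error(linear_baseline(tg, T_start = 10, T_end = -25),
               "above the sampled range")
  expect_error(linear_baseline(tg, T_start = -1, T_end = -80),
               "outside the sampled range")
})

test_that("latent-heat integration matches closed-form areas and flags the
           sign convention", {
  n <- 400
  # rectangular exotherm: 10 mW for 30 s (trapezoid-exact edges), 10 mg
  sig <- rep(0, n); sig[31:60 + 1] <- -10  # t = 30..59 s inclusive
  tg <- ramp_tg(sig)
  bl <- linear_baseline(tg, T_start = -1, T_end = -25)
  expect_equal(integrate_latent_heat(tg, bl)$latent_heat_mJ_mg, 30,
               tolerance = 1e-12)
  # flipped convention: the integral comes out negative and is rejected
  tg_bad <- thermogram(tg$time_s, tg$temperature_C, tg$heat_flow_mW,
                       sample_mass_mg = 10, cooling_rate = 5,
                       exo_down = FALSE)
  expect_error(integrate_latent_heat(
    tg_bad, linear_baseline(tg_bad, T_start = -1, T_end = -25)),
    "sign convention")
})

test_that("cumulative release curve normalises to one and ramps linearly for
           a rectangular exotherm", {
  n <- 400
  sig <- rep(0, n); sig[31:60 + 1] <- -10
  tg <- ramp_tg(sig)
  cv <- cumulative_release_curve(tg, linear_baseline(tg, T_start = -1,
                                                     T_end = -25))
  expect_equal(cv$fraction[nrow(cv)], 1)
  expect_true(all(diff(cv$fraction) >= 0))
  # within the rectangle the cumulative fraction is linear in time
  mid <- which(cv$fraction > 0.1 & cv$fraction < 0.9)
  expect_equal(diff(cv$fraction[mid]), rep(diff(cv$fraction[mid])[1],
                                           length(mid) - 1),
               tolerance = 1e-10)
})

test_that("sigmoidal baseline reduces to the linear one for equal trends and
           transitions monotonically across a step", {
  n <- 500
  tt <- seq(0, n - 1)
  hump <- -8 * exp(-((tt - 200) / 25)^2)
  tg <- ramp_tg(0.4 + hump)
  lin <- linear_baseline(tg, T_start = -5, T_end = -30)
  sig <- sigmoidal_baseline(tg, T_start = -5, T_end = -30)
  expect_lt(max(abs(sig$values - lin$values)), 1e-9)
  expect_lte(sig$iterations, 5)
  # instrument step of -2 mW across the transition: the baseline walks
  # monotonically from the pre to the post level
  step <- -2 * (1 + tanh((tt - 200) / 25)) / 2
  tg2 <- ramp_tg(0.4 + hump + step)
  sig2 <- sigmoidal_baseline(tg2, T_start = -5, T_end = -30)
  expect_true(all(diff(sig2$values) <= 1e-9))
  expect_equal(sig2$values[1], 0.4, tolerance = 1e-3)
  expect_equal(sig2$values[length(sig2$values)], -1.6, tolerance = 1e-3)
  # convergence is iterative and reported
  expect_true(is.finite(sig2$iterations))
  expect_error(sigmoidal_baseline(tg2, T_start = -5, T_end = -30,
                                  max_iter = 1), "did not converge")
})

test_that("synthetic thermograms round-trip through baselines to the
           generating release curve", {
  pbs <- solution_spec("1xPBS", 0.2853)
  # fast-saturating kinetics: the exotherm completes well inside both
  # baseline windows, so truncation bias is negligible
  p <- avrami_params(0.1, 8, 1.5, pbs$Tph)
  tg <- generate_thermogram(synth_spec(pbs, 5, model = p,
                                       nucleation_temp = -8))
  for (make in list(linear_baseline, sigmoidal_baseline)) {
    bl <- make(tg)
    cv <- cumulative_release_curve(tg, bl)
    ref <- latent_heat_fraction(cv$temperature, p, 5) /
      latent_heat_fraction(min(cv$temperature), p, 5)
    expect_lt(max(abs(cv$fraction - ref)), 0.01)
  }
  # Tph anchor defaults need an attached solution
  tg_bare <- thermogram(tg$time_s, tg$temperature_C, tg$heat_flow_mW,
                        sample_mass_mg = 10, cooling_rate = 5)
  expect_error(linear_baseline(tg_bare), "T_start")
})

test_that("sigmoidal integration sits below linear on a slow-tailed
           exotherm, mirroring the reported ordering", {
  pbs <- solution_spec("1xPBS", 0.2853)
  p <- avrami_params(0.53, 3.3, 1.5, pbs$Tph)
  tg <- generate_thermogram(synth_spec(pbs, 5, model = p,
                                       nucleation_temp = -8))
  lin <- integrate_latent_heat(tg, linear_baseline(tg))
  sig <- integrate_latent_heat(tg, sigmoidal_baseline(tg))
  expect_lt(sig$latent_heat_mJ_mg, lin$latent_heat_mJ_mg)
  expect_equal(lin$latent_heat_mJ_mg, 335, tolerance = 0.02)
})
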