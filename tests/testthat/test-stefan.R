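p5 <- stefan_params(cooling_rate = 5)

test_that("dimensionless groups follow their definitions", {
  g <- dimensionless_groups(p5)
  # direct arithmetic with B = 5 K/min, H = 5e-4 m, Tph = 272.62 K
  expect_equal(g$M, 1.858 * 0.2853 / p5$Tph, tolerance = 1e-12)
  expect_equal(g$stefan_number, 335 / (p5$Tph * 4.18), tolerance = 1e-12)
  expect_equal(g$k_ratio, 2.22 / 0.556, tolerance = 1e-12)
  # epsilon with a 1e-7 m^2/s thermal diffusivity lands at ~7.6e-4
  pe <- stefan_params(cooling_rate = 5, D_T_liquid = 1e-7)
  expect_equal(dimensionless_groups(pe)$epsilon_liquid,
               5 * (5e-4)^2 / (pe$Tph * 1e-7 * 60), tolerance = 1e-12)
  expect_lt(abs(dimensionless_groups(pe)$epsilon_liquid - 7.6e-4), 1e-4)
  # quasi-steady-heat assumption: epsilon tiny, gamma2 not
  expect_lt(g$epsilon_liquid, 1e-3)
  expect_gt(g$gamma2, 1)
})

test_that("viscosity and diffusivity models evaluate and trend correctly", {
  expect_equal(water_viscosity(298), 6.627e-4 * exp(1.807e4 / (8.314 * 298)),
               tolerance = 1e-12)
  expect_equal(signif(water_viscosity(298), 1), 1)  # ~1 cP at 298 K
  expect_equal(water_viscosity(273), 1.9005, tolerance = 1e-4)
  tt <- seq(250, 300, by = 5)
  expect_true(all(diff(water_viscosity(tt)) < 0))
  expect_equal(solute_diffusivity(298), 9.17e-14 * 298 / water_viscosity(298),
               tolerance = 1e-12)
  expect_true(all(diff(solute_diffusivity(tt)) > 0))
})

test_that("gamma2 tracks the cooling liquid and supports a constant mode", {
  tt <- seq(0, 0.12, length.out = 10)
  g2 <- gamma2_at(tt, p5)
  expect_true(all(diff(g2) > 0))  # colder -> more viscous -> slower diffusion
  expect_equal(gamma2_at(tt, p5, mode = "constant"),
               rep(gamma2_at(0, p5), length(tt)), tolerance = 1e-12)
  expect_equal(gamma2_at(0.05, p5, scale = 0.5), 0.5 * gamma2_at(0.05, p5),
               tolerance = 1e-12)
  expect_error(gamma2_at(1.5, p5), "positive")
})

test_that("a flat concentration profile leaves the front at rest", {
  st <- stefan_init(p5, 50)
  st1 <- stefan_step(st, p5, 1e-5)
  expect_identical(st1$Zdot, 0)
  expect_identical(st1$Z, 0)
  expect_equal(st1$t, 1e-5)
  # interior barely perturbed by one step of the Dirichlet ramp
  expect_lt(max(abs(st1$c[-1] - 1)), 0.01)
})

test_that("solute rejection builds up at the interface and advances the
           front", {
  st <- stefan_init(p5, 50)
  for (i in 1:20) st <- stefan_step(st, p5, 1e-5)
  expect_gt(st$c[1], 1)
  grad0 <- (-3 * st$c[1] + 4 * st$c[2] - st$c[3]) / (2 * st$h)
  expect_lt(grad0, 0)
  expect_gt(st$Zdot, 0)
  expect_gt(st$Z, 0)
  # interface concentration pinned to the liquidus value at every step
  expect_equal(st$c[1], 1 + st$t / st$M, tolerance = 1e-14)
})

test_that("the stepper matches an independent dense-matrix integration of
           the semi-discrete system", {
  for (far in c("mirror", "paper")) {
    for (N in c(4, 6, 8)) {
      s_pkg <- stefan_init(p5, N)
      s_ref <- stefan_init(p5, N)
      worst <- 0
      for (i in 1:40) {
        s_pkg <- stefan_step(s_pkg, p5, 1e-5, far_ghost = far,
                             gamma2_scale = 1e-4)
        s_ref <- dense_stefan_step(s_ref, p5, 1e-5, gamma2_scale = 1e-4,
                                   far = far)
        worst <- max(worst, abs(s_pkg$Z - s_ref$Z),
                     max(abs(s_pkg$c - s_ref$c)))
      }
      expect_lt(worst, 1e-10)
    }
  }
})

test_that("time step violating the advection CFL bound is rejected unless
           adaptive", {
  st <- stefan_init(p5, 100)
  # spin up in a fast-front regime so Zdot is appreciable
  for (i in 1:10) st <- stefan_step(st, p5, 1e-5, gamma2_scale = 1e-6,
                                    adapt = TRUE)
  expect_error(stefan_step(st, p5, 1, gamma2_scale = 1e-6), "CFL")
  st2 <- stefan_step(st, p5, 1, gamma2_scale = 1e-6, adapt = TRUE)
  expect_lte(st2$dt_used, st2$cfl_bound)
})

test_that("integration is first order in time and converged in space at
           reference settings", {
  tf <- 0.03
  z1 <- stefan_solve(p5, N = 60, dt = 2e-5, gamma2_scale = 2.17e-4,
                     t_final = tf)
  z2 <- stefan_solve(p5, N = 60, dt = 1e-5, gamma2_scale = 2.17e-4,
                     t_final = tf)
  z3 <- stefan_solve(p5, N = 60, dt = 5e-6, gamma2_scale = 2.17e-4,
                     t_final = tf)
  e12 <- abs(z1$trajectory$Z[nrow(z1$trajectory)] -
               z2$trajectory$Z[nrow(z2$trajectory)])
  e23 <- abs(z2$trajectory$Z[nrow(z2$trajectory)] -
               z3$trajectory$Z[nrow(z3$trajectory)])
  expect_gt(e12 / e23, 1.3)  # successive differences shrink ~linearly in dt
  expect_lt(e12 / e23, 3.5)
  # doubling N changes the final front position by well under 1%
  n1 <- stefan_solve(p5, N = 100, dt = 1e-5, gamma2_scale = 2.17e-4)
  n2 <- stefan_solve(p5, N = 200, dt = 1e-5, gamma2_scale = 2.17e-4)
  expect_lt(abs(n1$trajectory$Z[nrow(n1$trajectory)] -
                  n2$trajectory$Z[nrow(n2$trajectory)]) /
              n2$trajectory$Z[nrow(n2$trajectory)], 0.01)
})

test_that("discrete solute-conservation drift shrinks under grid
           refinement", {
  tf <- 0.03
  drifts <- vapply(c(50, 100, 200), function(N)
    stefan_solve(p5, N = N, dt = 2e-5,
                 t_final = tf)$diagnostics$max_conservation_drift,
    numeric(1))
  expect_true(all(diff(drifts) < 0))
})

test_that("the quasi-equilibrium closed form reproduces the lever rule and
           Z stays monotone", {
  eq <- stefan_solve(p5, mode = "equilibrium")
  pbs <- solution_spec("1xPBS", p5$osmolality)
  f <- equilibrium_release_fraction(eq$trajectory$temperature, pbs)
  expect_equal(eq$trajectory$Z, f, tolerance = 1e-10)
  # at the time the liquid reaches 263.15 K the closed form equals the
  # lever-rule frozen fraction 1 - m c0 / 10
  M <- 1.858 * 0.2853 / p5$Tph
  t10 <- (p5$Tph - 263.15) / p5$Tph
  expect_equal(equilibrium_interface(t10, M), 1 - 1.858 * 0.2853 / 10,
               tolerance = 1e-10)
  full <- stefan_solve(p5, N = 80, dt = 2e-5, t_final = 0.05)
  expect_true(all(diff(full$trajectory$Z) >= 0))
})

test_that("percent released runs from zero to one against falling
           temperature", {
  res <- stefan_solve(p5, N = 80, dt = 2e-5, t_final = 0.05)
  cv <- percent_released(res)
  expect_identical(cv$fraction[1], 0)
  expect_identical(cv$fraction[nrow(cv)], 1)
  expect_true(all(diff(cv$temperature) < 0))
  expect_true(all(diff(cv$fraction) >= 0))
})
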