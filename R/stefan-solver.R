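# Semi-implicit finite-difference solver for the reduced moving-boundary
# solute-diffusion model on the mapped fixed domain delta in [0, 1].
#
# Semi-discrete system (delta_j = j h, h = 1/(N+1), c_0 at the interface):
#   dc_j/dt = -Zdot (delta_j - 1)/(1 - Z) * (c_{j+1} - c_{j-1})/(2h)
#             + (1/gamma^2) (1/(1 - Z))^2 * (c_{j+1} - 2 c_j + c_{j-1})/h^2
#   gamma^2 Zdot = -(1/(1 + t/M)) (1/(1 - Z)) dc/ddelta|_0
# with c_0 = 1 + t/M (liquidus at the quasi-steady liquid temperature),
# ghost c_{-1} = 3 c_0 - 3 c_1 + c_2 (quadratic extrapolation, giving the
# second-order one-sided interface gradient), and a zero-gradient far
# boundary via a ghost value. Time stepping: explicit Euler for Z and the
# advection term, backward Euler for diffusion (tridiagonal solve) --
# first order in time, second order in space.

# Tridiagonal solve for rows  lo_i x_{i-1} + dg_i x_i + up_i x_{i+1} = rhs_i
# (lo[1] and up[n] ignored), with an optional `extra` coefficient on
# x_{n-2} in the last row (needed by the "paper" far-ghost mode, whose
# last-row stencil touches c_{N-1}).
.tridiag_solve <- function(lo, dg, up, rhs, extra = 0) {
  n <- length(dg)
  P <- numeric(n); Q <- numeric(n)
  den <- dg[1]
  P[1] <- -up[1] / den
  Q[1] <- rhs[1] / den
  if (n > 2L) {
    for (i in 2:(n - 1)) {
      den <- dg[i] + lo[i] * P[i - 1]
      P[i] <- -up[i] / den
      Q[i] <- (rhs[i] - lo[i] * Q[i - 1]) / den
    }
  }
  lo_n <- lo[n]; rhs_n <- rhs[n]
  if (extra != 0 && n >= 3L) {
    lo_n <- lo_n + extra * P[n - 2]
    rhs_n <- rhs_n - extra * Q[n - 2]
  }
  den <- dg[n] + lo_n * P[n - 1]
  x <- numeric(n)
  x[n] <- (rhs_n - lo_n * Q[n - 1]) / den
  for (i in (n - 1):1) x[i] <- P[i] * x[i + 1] + Q[i]
  x
}

#' Initial state of the moving-boundary solver
#'
#' @param p A [stefan_params()].
#' @param N Number of interior grid intervals parameter: the grid is
#'   `delta_j = j h`, `j = 0..N+1`, with `h = 1/(N+1)`.
#' @return A list of class `stefan_state` with non-dimensional time `t`,
#'   interface position `Z`, concentration vector `c` (length `N + 2`,
#'   units of the initial concentration), grid data and the concentration
#'   scale `M`.
#' @export
stefan_init <- function(p, N) {
  stopifnot(inherits(p, "stefan_params"), N >= 3)
  h <- 1 / (N + 1)
  structure(
    list(t = 0, Z = 0, c = rep(1, N + 2), N = as.integer(N), h = h,
         delta = seq(0, 1, by = h), M = p$slope * p$osmolality / p$Tph,
         terminated = FALSE),
    class = "stefan_state"
  )
}

#' Advance the moving-boundary state by one time step
#'
#' One step of the semi-implicit scheme: (i) interface gradient from the
#' second-order one-sided stencil (ghost `c_{-1} = 3 c_0 - 3 c_1 + c_2`);
#' (ii) interface velocity from the solute-flux jump condition, with the
#' sign fixed so that solute rejection (concentration maximal at the
#' interface) advances the front, `Zdot >= 0`; (iii) explicit Euler update
#' of `Z`; (iv) concentration update with explicit advection and implicit
#' (backward Euler) diffusion via a tridiagonal solve; (v) Dirichlet
#' interface value `c_0 = 1 + t/M` at the new time and a zero-gradient
#' ghost at the far end.
#'
#' @param state A `stefan_state` from [stefan_init()] or a previous step.
#' @param p A [stefan_params()].
#' @param dt Time step (non-dimensional). With `adapt = FALSE` the step
#'   errors if `dt` violates the advection CFL bound
#'   `0.5 h (1 - Z) / |Zdot|`; with `adapt = TRUE` it is shortened to the
#'   bound instead.
#' @param gamma2_mode,gamma2_scale Passed to [gamma2_at()].
#' @param far_ghost Far-boundary ghost convention: `"mirror"` (default,
#'   `c_{N+2} = c_N`, the standard second-order zero-gradient closure) or
#'   `"paper"` (`c_{N+2} = c_{N-1}`).
#' @param adapt Shorten the step to the CFL bound instead of erroring.
#' @return The advanced `stefan_state`; its `dt_used`, `Zdot` and
#'   `cfl_bound` fields report the step just taken, and `terminated` is
#'   set when the front reaches `1 - h`.
#' @export
stefan_step <- function(state, p, dt,
                        gamma2_mode = c("temperature", "constant"),
                        gamma2_scale = 1,
                        far_ghost = c("mirror", "paper"),
                        adapt = FALSE) {
  stopifnot(inherits(state, "stefan_state"), inherits(p, "stefan_params"))
  gamma2_mode <- match.arg(gamma2_mode)
  far_ghost <- match.arg(far_ghost)
  N <- state$N; h <- state$h; M <- state$M
  cc <- state$c; Z <- state$Z; t <- state$t

  g2 <- gamma2_at(t, p, mode = gamma2_mode, scale = gamma2_scale)
  grad0 <- (-3 * cc[1] + 4 * cc[2] - cc[3]) / (2 * h)
  Zdot_raw <- -grad0 / (g2 * (1 + t / M) * (1 - Z))
  Zdot <- max(Zdot_raw, 0)

  cfl <- if (Zdot > 0) 0.5 * h * (1 - Z) / Zdot else Inf
  if (dt > cfl) {
    if (adapt) dt <- cfl
    else stop(sprintf(
      "time step %.3g violates the advection CFL bound %.3g", dt, cfl),
      call. = FALSE)
  }

  Z_new <- Z + dt * Zdot
  t_new <- t + dt
  if (Z_new >= 1 - h) {
    state$terminated <- TRUE
    state$dt_used <- dt; state$Zdot <- Zdot; state$cfl_bound <- cfl
    return(state)
  }

  # explicit advection at j = 1..N+1 (R indices 2..N+2)
  j <- 2:(N + 2)
  ghost_far <- if (far_ghost == "mirror") cc[N + 1] else cc[N]
  cpad <- c(cc, ghost_far)
  dcd <- (cpad[j + 1] - cpad[j - 1]) / (2 * h)
  adv <- -Zdot * (state$delta[j] - 1) / (1 - Z) * dcd
  rhs <- cc[j] + dt * adv

  # implicit diffusion at the new time level
  g2_new <- gamma2_at(t_new, p, mode = gamma2_mode, scale = gamma2_scale)
  r <- dt / (g2_new * (1 - Z_new)^2 * h^2)
  c0_new <- 1 + t_new / M
  n_unk <- N + 1
  dg <- rep(1 + 2 * r, n_unk)
  lo <- rep(-r, n_unk)
  up <- rep(-r, n_unk)
  rhs[1] <- rhs[1] + r * c0_new
  extra <- 0
  if (far_ghost == "mirror") {
    lo[n_unk] <- -2 * r           # stencil c_N - 2 c_{N+1} + c_N
  } else {
    extra <- -r                   # stencil c_{N-1} - 2 c_{N+1} + c_N
  }
  x <- .tridiag_solve(lo, dg, up, rhs, extra = extra)

  state$t <- t_new
  state$Z <- Z_new
  state$c <- c(c0_new, x)
  state$dt_used <- dt
  state$Zdot <- Zdot
  state$Zdot_raw <- Zdot_raw
  state$cfl_bound <- cfl
  state
}

# non-dimensional total solute in the liquid: (1 - Z) * trapezoid of c
.solute_total <- function(state) {
  (1 - state$Z) * state$h *
    (sum(state$c) - (state$c[1] + state$c[length(state$c)]) / 2)
}

#' Closed-form quasi-equilibrium interface position
#'
#' In the fast-diffusion limit the liquid concentration is uniform at the
#' liquidus value `1 + t/M`; solute conservation then fixes the front at
#' \deqn{Z_{eq}(t) = 1 - \frac{1}{1 + t/M},}
#' which is exactly the lever-rule frozen fraction of the phase diagram.
#'
#' @param t Non-dimensional time(s).
#' @param M Concentration scale `m c0 / Tph`.
#' @return Interface position(s) in `[0, 1)`.
#' @export
equilibrium_interface <- function(t, M) 1 - 1 / (1 + t / M)

#' Solve the reduced moving-boundary freezing model
#'
#' Integrates the mapped-domain solute-diffusion system from a fully
#' liquid state (`Z = 0`, uniform concentration) until the liquid
#' temperature reaches 40 K below the phase-change temperature
#' (non-dimensional `t_final = 40 / Tph`), recording the interface
#' trajectory and conservation diagnostics. In `"equilibrium"` mode the
#' closed-form [equilibrium_interface()] trajectory is returned instead.
#'
#' @param p A [stefan_params()].
#' @param N Grid refinement; `N = 200` is the reference resolution.
#' @param dt Nominal time step; each step is additionally capped by the
#'   advection CFL bound, so the effective step adapts during the fast
#'   early transient.
#' @param mode `"full"` (default) or `"equilibrium"`.
#' @param gamma2_mode,gamma2_scale Passed to [gamma2_at()].
#' @param far_ghost Far-boundary ghost convention (see [stefan_step()]).
#' @param t_final Non-dimensional end time; default `40 / Tph`.
#' @param n_records Approximate number of trajectory records kept.
#' @return An object of class `stefan_result`: list with `trajectory`
#'   (data frame of non-dimensional `t`, interface `Z`, dimensional
#'   `temperature` K), the final concentration profile `concentration` on
#'   grid `delta`, `params`, and `diagnostics` (max solute-conservation
#'   drift, step count, smallest/largest step used, early-termination
#'   flag, most negative raw interface velocity).
#' @export
stefan_solve <- function(p, N = 200, dt = 1e-5,
                         mode = c("full", "equilibrium"),
                         gamma2_mode = c("temperature", "constant"),
                         gamma2_scale = 1,
                         far_ghost = c("mirror", "paper"),
                         t_final = NULL, n_records = 800) {
  stopifnot(inherits(p, "stefan_params"))
  mode <- match.arg(mode)
  gamma2_mode <- match.arg(gamma2_mode)
  far_ghost <- match.arg(far_ghost)
  if (is.null(t_final)) t_final <- 40 / p$Tph

  if (mode == "equilibrium") {
    M <- p$slope * p$osmolality / p$Tph
    tt <- seq(0, t_final, length.out = n_records)
    Z <- equilibrium_interface(tt, M)
    return(structure(
      list(trajectory = data.frame(t = tt, Z = Z,
                                   temperature = p$Tph * (1 - tt)),
           concentration = NULL, delta = NULL, N = NA_integer_,
           params = p, mode = mode, gamma2_mode = gamma2_mode,
           gamma2_scale = gamma2_scale, far_ghost = far_ghost,
           diagnostics = list(max_conservation_drift = 0, steps = 0L,
                              dt_min = NA_real_, dt_max = NA_real_,
                              terminated_early = FALSE,
                              min_Zdot_raw = NA_real_)),
      class = "stefan_result"))
  }

  state <- stefan_init(p, N)
  checkpoints <- seq(0, t_final, length.out = n_records)
  next_cp <- 2L
  rec_t <- numeric(n_records + 8); rec_Z <- numeric(n_records + 8)
  rec_t[1] <- 0; rec_Z[1] <- 0; n_rec <- 1L
  drift_max <- 0
  dt_min <- Inf; dt_max <- 0
  min_Zdot_raw <- Inf
  steps <- 0L
  terminated_early <- FALSE

  while (state$t < t_final) {
    step_dt <- min(dt, t_final - state$t)
    state <- stefan_step(state, p, step_dt, gamma2_mode = gamma2_mode,
                         gamma2_scale = gamma2_scale,
                         far_ghost = far_ghost, adapt = TRUE)
    if (state$terminated) { terminated_early <- TRUE; break }
    steps <- steps + 1L
    dt_min <- min(dt_min, state$dt_used)
    dt_max <- max(dt_max, state$dt_used)
    min_Zdot_raw <- min(min_Zdot_raw, state$Zdot_raw)
    if (next_cp <= n_records && state$t >= checkpoints[next_cp]) {
      n_rec <- n_rec + 1L
      rec_t[n_rec] <- state$t; rec_Z[n_rec] <- state$Z
      drift_max <- max(drift_max, abs(.solute_total(state) - 1))
      while (next_cp <= n_records && checkpoints[next_cp] <= state$t)
        next_cp <- next_cp + 1L
    }
  }
  if (rec_t[n_rec] < state$t) {
    n_rec <- n_rec + 1L
    rec_t[n_rec] <- state$t; rec_Z[n_rec] <- state$Z
    drift_max <- max(drift_max, abs(.solute_total(state) - 1))
  }
  tt <- rec_t[seq_len(n_rec)]; Z <- rec_Z[seq_len(n_rec)]

  structure(
    list(trajectory = data.frame(t = tt, Z = Z,
                                 temperature = p$Tph * (1 - tt)),
         concentration = state$c, delta = state$delta, N = state$N,
         params = p, mode = mode, gamma2_mode = gamma2_mode,
         gamma2_scale = gamma2_scale, far_ghost = far_ghost,
         diagnostics = list(max_conservation_drift = drift_max,
                            steps = steps, dt_min = dt_min,
                            dt_max = dt_max,
                            terminated_early = terminated_early,
                            min_Zdot_raw = min_Zdot_raw)),
    class = "stefan_result"
  )
}

#' @export
print.stefan_result <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "<stefan_result> %s mode, B = %g K/min, N = %s: Z reaches %.4f at t = %.4g\n",
    x$mode, x$params$cooling_rate,
    if (is.na(x$N)) "-" else x$N, tr$Z[nrow(tr)], tr$t[nrow(tr)]))
  if (x$mode == "full")
    cat(sprintf(
      "  %d steps (dt %.2g .. %.2g), solute-conservation drift %.3g%s\n",
      x$diagnostics$steps, x$diagnostics$dt_min, x$diagnostics$dt_max,
      x$diagnostics$max_conservation_drift,
      if (x$diagnostics$terminated_early) ", terminated at Z = 1 - h"
      else ""))
  invisible(x)
}

#' Percent of latent heat released along a freezing simulation
#'
#' Normalises the interface trajectory by its final value,
#' `Z(t) / Z(t_final)`, and reports it against the dimensional
#' temperature `T = Tph (1 - t)`: the fraction of the run's total latent
#' heat released by the time the sample has cooled to each temperature.
#'
#' @param res A [stefan_solve()] result.
#' @return A [release_curve()] (final value exactly 1).
#' @export
percent_released <- function(res) {
  stopifnot(inherits(res, "stefan_result"))
  tr <- res$trajectory
  Z_final <- tr$Z[nrow(tr)]
  if (Z_final <= 0)
    stop("the front never moved (Z(t_final) = 0); nothing to normalise",
         call. = FALSE)
  keep <- !duplicated(tr$t)
  release_curve(tr$temperature[keep], tr$Z[keep] / Z_final,
                cooling_rate = res$params$cooling_rate,
                solution = solution_spec("stefan", res$params$osmolality,
                                         res$params$slope))
}
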