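#' Specification for synthetic DSC data
#'
#' Describes a synthetic experiment: the solution, the cooling rate, the
#' forward model that produces the release fraction, and the instrument/
#' noise parameters. The generator emulates the pre-nucleated constant-
#' cooling-rate protocol: a 5 K/min search ramp from +4 degC until ice
#' nucleates (a sharp exothermic spike between -6 and -12 degC), an
#' equilibration hold at the phase-change temperature, then the measuring
#' ramp at the requested rate down to -50 degC with the freezing exotherm
#' riding on a slowly drifting instrument baseline.
#'
#' @param solution A [solution_spec()].
#' @param cooling_rate Measuring-ramp cooling rate B in K/min.
#' @param model Forward model for the release fraction: the string
#'   `"equilibrium"` (lever rule; for pure water a smoothed step of width
#'   `pure_water_width` K standing in for instrument smearing of the
#'   delta-function release), an [avrami_params()] object, or a
#'   [stefan_params()] object (solved at generation time; its fraction is
#'   differentiated by finite differences).
#' @param total_latent_heat Heat released over the measuring ramp, mJ/mg
#'   (default 335, the pure-ice calibration value). The model fraction is
#'   normalised to 1 at the end of the ramp so the integrated exotherm
#'   equals this value exactly.
#' @param sample_mass Sample mass in mg (default 10).
#' @param sampling_hz Sampling rate (default 10 Hz).
#' @param noise_fraction Gaussian noise s.d. on release fractions
#'   (dimensionless, for [generate_release_curves()]).
#' @param noise_mW Gaussian noise s.d. on the heat-flow signal (mW, for
#'   [generate_thermogram()]).
#' @param baseline_offset,baseline_slope Instrument baseline offset (mW)
#'   and drift (mW/min).
#' @param nucleation_temp Nucleation temperature in degC, or `NULL` to
#'   draw uniformly from \[-12, -6\].
#' @param replicates Number of replicate curves (default 1; the study
#'   convention is 6).
#' @param seed RNG seed; mandatory whenever any noise s.d. is positive.
#' @param n_points Temperature grid size for release curves (default 100,
#'   uniform from Tph to Tph - 40).
#' @param hold_s Equilibration hold at Tph in seconds.
#' @param start_temp,end_temp Start of the search ramp and end of the
#'   measuring ramp, degC.
#' @param pure_water_width Smoothing width (K) of the pure-water release
#'   step.
#' @param spike_width_s,spike_rel Nucleation spike width (s) and
#'   amplitude relative to the exotherm peak (cosmetic; the spike only
#'   exercises the detector).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(solution, cooling_rate, model = "equilibrium",
                       total_latent_heat = 335, sample_mass = 10,
                       sampling_hz = 10, noise_fraction = 0, noise_mW = 0,
                       baseline_offset = 0.5, baseline_slope = 0.05,
                       nucleation_temp = NULL, replicates = 1, seed = NULL,
                       n_points = 100, hold_s = 30, start_temp = 4,
                       end_temp = -50, pure_water_width = 0.5,
                       spike_width_s = 2, spike_rel = 5) {
  stopifnot(inherits(solution, "solution_spec"))
  if (!(identical(model, "equilibrium") || inherits(model, "avrami_params") ||
        inherits(model, "stefan_params")))
    stop('`model` must be "equilibrium", an avrami_params or a ',
         "stefan_params object", call. = FALSE)
  if (noise_fraction < 0 || noise_mW < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if ((noise_fraction > 0 || noise_mW > 0) && is.null(seed))
    stop("`seed` is mandatory when any noise s.d. is positive",
         call. = FALSE)
  structure(
    list(solution = solution, cooling_rate = cooling_rate, model = model,
         total_latent_heat = total_latent_heat, sample_mass = sample_mass,
         sampling_hz = sampling_hz, noise_fraction = noise_fraction,
         noise_mW = noise_mW, baseline_offset = baseline_offset,
         baseline_slope = baseline_slope, nucleation_temp = nucleation_temp,
         replicates = as.integer(replicates), seed = seed,
         n_points = n_points, hold_s = hold_s, start_temp = start_temp,
         end_temp = end_temp, pure_water_width = pure_water_width,
         spike_width_s = spike_width_s, spike_rel = spike_rel),
    class = "synth_spec"
  )
}

# model release fraction at temperatures (K); stefan result is reused when
# supplied to avoid re-solving
.model_fraction <- function(spec, temp_K, stefan_res = NULL) {
  sol <- spec$solution
  if (identical(spec$model, "equilibrium")) {
    if (sol$osmolality == 0) {
      w <- spec$pure_water_width
      dT <- 273.15 - temp_K
      return(ifelse(dT <= 0, 0,
                    ifelse(dT >= w, 1, 0.5 * (1 - cos(pi * dT / w)))))
    }
    return(equilibrium_release_fraction(temp_K, sol))
  }
  if (inherits(spec$model, "avrami_params"))
    return(latent_heat_fraction(temp_K, spec$model, spec$cooling_rate))
  if (is.null(stefan_res))
    stefan_res <- stefan_solve(spec$model)
  curve <- percent_released(stefan_res)
  out <- stats::approx(curve$temperature, curve$fraction, xout = temp_K,
                       rule = 2)$y
  out[temp_K >= spec$model$Tph] <- 0
  out
}

# d(fraction)/dt in 1/s along the measuring ramp, tau_s seconds after Tph
.model_dfdt <- function(spec, tau_s, stefan_res = NULL) {
  sol <- spec$solution
  B <- spec$cooling_rate
  if (identical(spec$model, "equilibrium")) {
    dT <- B / 60 * tau_s
    if (sol$osmolality == 0) {
      w <- spec$pure_water_width
      dfdT <- ifelse(dT <= 0 | dT >= w, 0, pi / (2 * w) * sin(pi * dT / w))
    } else {
      mc0 <- sol$slope * sol$osmolality
      dfdT <- mc0 / (mc0 + dT)^2
    }
    return(dfdT * B / 60)
  }
  if (inherits(spec$model, "avrami_params")) {
    m <- spec$model
    per_min <- m$time_unit == "minutes"
    tau_u <- if (per_min) tau_s / 60 else tau_s
    B_u <- if (per_min) B else B / 60  # K per time unit
    dT <- B_u * tau_u
    a <- 1 - m$A / (dT + m$A)
    da <- m$A * B_u / (dT + m$A)^2
    eb <- exp(-m$k * tau_u^m$n)
    b <- 1 - eb
    db <- ifelse(tau_u > 0, m$k * m$n * tau_u^(m$n - 1) * eb, 0)
    dLdu <- da * b + a * db
    return(if (per_min) dLdu / 60 else dLdu)
  }
  # stefan: central finite differences of the solved release fraction
  if (is.null(stefan_res)) stefan_res <- stefan_solve(spec$model)
  eps <- max(diff(range(tau_s)) * 1e-4, 1e-3)
  temp_of <- function(s) spec$model$Tph - B / 60 * s
  fp <- .model_fraction(spec, temp_of(tau_s + eps), stefan_res)
  fm <- .model_fraction(spec, temp_of(pmax(tau_s - eps, 0)), stefan_res)
  (fp - fm) / (tau_s + eps - pmax(tau_s - eps, 0))
}

#' Generate synthetic release curves
#'
#' Evaluates the chosen forward model on a uniform temperature grid from
#' the phase-change temperature down 40 K, adds i.i.d. Gaussian noise
#' (clipped to `[0, 1]`) per replicate, and returns one
#' [release_curve()] per replicate. Deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A list of [release_curve()] objects, one per replicate.
#' @examples
#' pbs <- solution_spec("1xPBS", 0.2853)
#' model <- avrami_params(0.53, 3.3, 1.5, pbs$Tph)
#' sp <- synth_spec(pbs, cooling_rate = 5, model = model,
#'                  noise_fraction = 0.01, replicates = 6, seed = 1)
#' curves <- generate_release_curves(sp)
#' @export
generate_release_curves <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  Tph <- if (inherits(spec$model, "avrami_params")) spec$model$Tph
         else if (inherits(spec$model, "stefan_params")) spec$model$Tph
         else spec$solution$Tph
  grid <- seq(Tph, Tph - 40, length.out = spec$n_points)
  stefan_res <- if (inherits(spec$model, "stefan_params"))
    stefan_solve(spec$model) else NULL
  f <- .model_fraction(spec, grid, stefan_res)
  tu <- if (inherits(spec$model, "avrami_params")) spec$model$time_unit
        else "minutes"
  lapply(seq_len(spec$replicates), function(i) {
    frac <- f
    if (spec$noise_fraction > 0)
      frac <- pmin(pmax(f + stats::rnorm(length(f), 0, spec$noise_fraction),
                        0), 1)
    release_curve(grid, frac, cooling_rate = spec$cooling_rate,
                  replicate = i, solution = spec$solution, time_unit = tu)
  })
}

#' Generate a synthetic DSC thermogram
#'
#' Builds the full three-segment record (search ramp with nucleation
#' spike, equilibration hold, measuring ramp) with heat flow
#' \deqn{q(t) = b(t) - m_s L_{tot}\,\frac{df}{dt}}
#' under the exo-down convention, where `b(t)` is the drifting instrument
#' baseline and `f` the model release fraction normalised to 1 at the end
#' of the measuring ramp. Gaussian mW noise is added when requested;
#' deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [thermogram()].
#' @export
generate_thermogram <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sol <- spec$solution
  Tph_C <- (if (inherits(spec$model, "avrami_params")) spec$model$Tph
            else if (inherits(spec$model, "stefan_params")) spec$model$Tph
            else sol$Tph) - 273.15
  fs <- spec$sampling_hz
  dstep <- 1 / fs
  B <- spec$cooling_rate

  T_nuc <- spec$nucleation_temp
  if (is.null(T_nuc)) T_nuc <- stats::runif(1, -12, -6)
  if (T_nuc > spec$start_temp)
    stop("nucleation temperature above the start temperature",
         call. = FALSE)

  # segment A: search ramp at 5 K/min from start_temp to the nucleation
  # temperature; segment B: hold at Tph; segment C: measuring ramp at B
  durA <- (spec$start_temp - T_nuc) * 60 / 5
  tA <- seq(0, durA, by = dstep)
  TA <- spec$start_temp - 5 / 60 * tA
  tB <- if (spec$hold_s >= dstep)
    seq(dstep, by = dstep, length.out = floor(spec$hold_s * fs)) + tA[length(tA)]
  else numeric(0)
  TB <- rep(Tph_C, length(tB))
  t0C <- if (length(tB)) tB[length(tB)] else tA[length(tA)]
  durC <- (Tph_C - spec$end_temp) * 60 / B
  tC <- seq(dstep, by = dstep, length.out = floor(durC * fs)) + t0C
  TC <- Tph_C - B / 60 * (tC - t0C)

  time <- c(tA, tB, tC)
  temp <- c(TA, TB, TC)
  baseline <- spec$baseline_offset + spec$baseline_slope * time / 60

  stefan_res <- if (inherits(spec$model, "stefan_params"))
    stefan_solve(spec$model) else NULL
  tau <- tC - t0C
  dfdt <- .model_dfdt(spec, tau, stefan_res)
  f_end <- .model_fraction(spec, TC[length(TC)] + 273.15, stefan_res)
  if (f_end <= 0)
    stop("the forward model releases no heat over the measuring ramp",
         call. = FALSE)
  dfdt_norm <- dfdt / f_end

  in_release <- sum(dfdt_norm > 1e-6 * max(dfdt_norm))
  if (in_release < 50)
    stop(sprintf(paste0("sampling rate too low: only %d samples resolve ",
                        "the release window (need >= 50)"), in_release),
         call. = FALSE)

  excess <- spec$sample_mass * spec$total_latent_heat * dfdt_norm  # mW
  heat <- baseline
  heat[(length(tA) + length(tB) + 1):length(time)] <-
    heat[(length(tA) + length(tB) + 1):length(time)] - excess

  # triangular nucleation spike centred on the end of the search ramp
  spike_amp <- spec$spike_rel * max(excess)
  spike_centre <- tA[length(tA)]
  w <- spec$spike_width_s / 2
  spike <- pmax(0, 1 - abs(time - spike_centre) / w) * spike_amp
  heat <- heat - spike

  if (spec$noise_mW > 0)
    heat <- heat + stats::rnorm(length(heat), 0, spec$noise_mW)

  thermogram(time, temp, heat, sample_mass_mg = spec$sample_mass,
             cooling_rate = B, solution = sol, exo_down = TRUE)
}
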