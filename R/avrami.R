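#' Parameters of the separable temperature-time release model
#'
#' The composite model factorises the cumulative latent-heat release into
#' a temperature part and a kinetic (time) part,
#' \deqn{L(T, t) = \alpha(T)\,\beta(t),}
#' with \eqn{\alpha(T) = 1 - A/((T_{ph} - T) + A)} (phase-diagram-like
#' temperature dependence) and \eqn{\beta(t) = 1 - e^{-k t^n}} (Avrami/JMAK
#' kinetics for pre-nucleated, "site-saturated" samples).
#'
#' @param A Temperature constant (K), positive. When \eqn{A = m c_0},
#'   \eqn{\alpha} coincides exactly with the lever-rule release fraction
#'   of the binary phase diagram.
#' @param k Avrami rate constant, in `time_unit^-n`, positive.
#' @param n Avrami time exponent, positive and dimensionless; 1.5 is the
#'   diffusion-controlled, site-saturated value.
#' @param Tph Phase-change temperature (K), at most 273.15.
#' @param time_unit Unit of the elapsed time fed to \eqn{\beta}:
#'   `"minutes"` (default) or `"seconds"`. The magnitude of `k` is tied to
#'   this choice; fits and forward simulations must use the same unit.
#' @return An object of class `avrami_params`.
#' @examples
#' avrami_params(A = 0.53, k = 3.3, n = 1.5, Tph = 272.62)
#' @export
avrami_params <- function(A, k, n, Tph, time_unit = c("minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  for (nm in c("A", "k", "n", "Tph")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (A <= 0) stop("`A` must be positive", call. = FALSE)
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (Tph > 273.15)
    stop("`Tph` must not exceed 273.15 K", call. = FALSE)
  structure(list(A = A, k = k, n = n, Tph = Tph, time_unit = time_unit),
            class = "avrami_params")
}

#' @export
print.avrami_params <- function(x, ...) {
  cat(sprintf(
    "<avrami_params> A = %.4g K, k = %.4g %s^-%g, n = %.4g, Tph = %.2f K\n",
    x$A, x$k, substr(x$time_unit, 1, 3), x$n, x$n, x$Tph))
  invisible(x)
}

#' Temperature dependence of latent-heat release
#'
#' \eqn{\alpha(T) = 1 - A / ((T_{ph} - T) + A)} for \eqn{T < T_{ph}}, and 0
#' otherwise. Strictly increasing as the sample cools, bounded in
#' \eqn{[0, 1)}.
#'
#' @param temperature Temperature(s) in kelvin.
#' @param A Temperature constant (K), positive.
#' @param Tph Phase-change temperature (K).
#' @return Release fraction(s).
#' @export
avrami_alpha <- function(temperature, A, Tph) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("`A` must be a single positive number", call. = FALSE)
  ifelse(temperature >= Tph, 0, 1 - A / ((Tph - temperature) + A))
}

#' Avrami kinetic (time) dependence of latent-heat release
#'
#' \eqn{\beta(t) = 1 - \exp(-k t^n)}: 0 at \eqn{t = 0}, strictly
#' increasing, saturating at 1.
#'
#' @param t Elapsed time(s) since the phase-change temperature was
#'   crossed, in the unit `k` is expressed in. Must be non-negative.
#' @param k Rate constant, positive.
#' @param n Time exponent, positive.
#' @return Transformed fraction(s).
#' @export
avrami_beta <- function(t, k, n) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative and finite", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("`n` must be a single positive number", call. = FALSE)
  1 - exp(-k * t^n)
}

#' Elapsed time at a temperature under constant cooling
#'
#' Time since the sample crossed the phase-change temperature while being
#' cooled at `cooling_rate` K/min: \eqn{(T_{ph} - T) \cdot 60 / B} in
#' seconds mode, \eqn{(T_{ph} - T)/B} in minutes mode.
#'
#' @param temperature Temperature(s) in kelvin, at most `Tph`.
#' @param Tph Phase-change temperature (K).
#' @param cooling_rate Cooling rate B in K/min, positive.
#' @param time_unit `"minutes"` (default) or `"seconds"`.
#' @return Elapsed time(s) in the requested unit.
#' @export
time_from_temperature <- function(temperature, Tph, cooling_rate,
                                  time_unit = c("minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  if (!is.numeric(cooling_rate) || length(cooling_rate) != 1L ||
      cooling_rate <= 0)
    stop("`cooling_rate` must be a single positive number (K/min)",
         call. = FALSE)
  dT <- Tph - temperature
  if (any(dT < 0))
    stop("`temperature` must not exceed `Tph`", call. = FALSE)
  if (time_unit == "seconds") dT * 60 / cooling_rate else dT / cooling_rate
}

#' Composite latent-heat release fraction under constant cooling
#'
#' Evaluates \eqn{L(T, t) = \alpha(T)\,\beta(t)} along a constant-rate
#' cooling ramp, with the elapsed time tied to temperature through the
#' cooling rate. The result never exceeds \eqn{\alpha(T)} and approaches
#' it as the cooling rate goes to zero (quasi-equilibrium limit).
#'
#' @param temperature Temperature(s) in kelvin.
#' @param params An [avrami_params()] object.
#' @param cooling_rate Cooling rate B in K/min, positive.
#' @return Release fraction(s).
#' @examples
#' p <- avrami_params(0.53, 3.3, 1.5, 272.62)
#' latent_heat_fraction(seq(272, 240, by = -2), p, cooling_rate = 5)
#' @export
latent_heat_fraction <- function(temperature, params, cooling_rate) {
  stopifnot(inherits(params, "avrami_params"))
  out <- numeric(length(temperature))
  below <- temperature < params$Tph
  if (any(below)) {
    tt <- time_from_temperature(temperature[below], params$Tph,
                                cooling_rate, params$time_unit)
    out[below] <- avrami_alpha(temperature[below], params$A, params$Tph) *
      avrami_beta(tt, params$k, params$n)
  }
  out
}

#' Linearised Avrami diagnostic of a release curve
#'
#' Divides the measured release fraction by the temperature part
#' \eqn{\alpha(T)} to isolate the kinetic part \eqn{\hat\beta}, then
#' applies the double-log transform: points
#' \eqn{(\ln t,\ \ln[-\ln(1 - \hat\beta)])} fall on a straight line with
#' slope `n` and intercept \eqn{\ln k} when the kinetics are Avrami-like.
#' Samples with \eqn{t \le 0} or \eqn{\hat\beta \notin (0, 1)} are dropped
#' (the transform is undefined there) and counted, never imputed.
#'
#' @param curve A [release_curve()].
#' @param A Temperature constant (K).
#' @param Tph Phase-change temperature (K); defaults to the curve's
#'   solution if present.
#' @param time_unit Time unit; defaults to the curve's convention.
#' @return An object of class `avrami_linearized`: list with `points`
#'   (data frame of `log_time`, `log_log`), `n_dropped`, and the
#'   least-squares `slope` and `intercept` of the points.
#' @export
avrami_linearize <- function(curve, A, Tph = NULL, time_unit = NULL) {
  stopifnot(inherits(curve, "release_curve"))
  if (is.null(Tph)) {
    sol <- attr(curve, "solution")
    if (is.null(sol))
      stop("`Tph` must be given when the curve has no solution attached",
           call. = FALSE)
    Tph <- sol$Tph
  }
  if (is.null(time_unit)) time_unit <- attr(curve, "time_unit")
  B <- attr(curve, "cooling_rate")
  below <- curve$temperature < Tph
  tt <- rep(NA_real_, nrow(curve))
  tt[below] <- time_from_temperature(curve$temperature[below], Tph, B,
                                     time_unit)
  frac <- pmin(pmax(curve$fraction, 0), 1 - 1e-12)
  a <- avrami_alpha(curve$temperature, A, Tph)
  beta_hat <- ifelse(a > 0, frac / a, NA_real_)
  ok <- below & !is.na(tt) & tt > 0 & !is.na(beta_hat) &
    beta_hat > 0 & beta_hat < 1
  n_dropped <- nrow(curve) - sum(ok)
  if (sum(ok) < 2L)
    stop("fewer than 2 valid points survive the double-log transform",
         call. = FALSE)
  pts <- data.frame(log_time = log(tt[ok]),
                    log_log = log(-log(1 - beta_hat[ok])))
  fit <- stats::lm(log_log ~ log_time, data = pts)
  structure(
    list(points = pts, n_dropped = n_dropped,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1])),
    class = "avrami_linearized"
  )
}

#' @export
print.avrami_linearized <- function(x, ...) {
  cat(sprintf(
    "<avrami_linearized> %d points (%d dropped); slope (n) = %.4f, ",
    nrow(x$points), x$n_dropped, x$slope))
  cat(sprintf("intercept (ln k) = %.4f => k = %.4f\n",
              x$intercept, exp(x$intercept)))
  invisible(x)
}
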