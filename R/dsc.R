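# Thermogram processing: nucleation detection, baseline construction,
# enthalpy integration, cumulative release curves.

# trapezoidal integral of y over x
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

# running (cumulative) trapezoid, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + y[-1]) / 2))
}

# index range between the two baseline anchors: start anchor matched as the
# last sample at or above T_start (the moment the final cooling ramp leaves
# the phase-change temperature), end anchor as the nearest sampled
# temperature thereafter
.anchor_indices <- function(tg, T_start, T_end) {
  temp <- tg$temperature_C
  n <- length(temp)
  cand <- which(temp >= T_start)
  if (length(cand) == 0L)
    stop(sprintf("start anchor %.2f degC above the sampled range", T_start),
         call. = FALSE)
  i0 <- max(cand)
  if (i0 >= n || min(temp[i0:n]) > T_end + 0.5)
    stop(sprintf("end anchor %.2f degC outside the sampled range", T_end),
         call. = FALSE)
  i1 <- i0 + which.min(abs(temp[(i0 + 1):n] - T_end))
  list(i0 = i0, i1 = i1)
}

.default_Tstart <- function(tg, T_start) {
  if (!is.null(T_start)) return(T_start)
  sol <- attr(tg, "solution")
  if (is.null(sol))
    stop("`T_start` must be given when the thermogram has no solution ",
         "attached (it defaults to the solution's phase-change temperature)",
         call. = FALSE)
  sol$Tph - 273.15
}

.excess_sign <- function(tg) if (attr(tg, "exo_down")) 1 else -1

#' Detect the nucleation spike in a thermogram
#'
#' Ice nucleation in an undercooled sample shows up as a sharp exothermic
#' spike, typically between -6 and -12 degC. The detector looks for the
#' largest exothermic excursion of the heat-flow signal relative to a
#' running median within the requested temperature window; broad features
#' (the main freezing exotherm) survive the median and are ignored.
#'
#' @param tg A [thermogram()].
#' @param window Temperature window (degC) to search, default `c(-12, -6)`.
#' @param prominence Minimum excursion (mW) below the running median for a
#'   spike to count. Default: 10 times the median absolute excursion in
#'   the window (robust to the spike itself), with a floor of `1e-9` mW.
#' @param median_k Width of the running median in samples (odd; default
#'   51). Must exceed the spike width for the spike to stand out.
#' @return A list with `index` (row in `tg`), `temperature_C` and
#'   `excursion_mW`, or `NULL` (with a message) when no excursion exceeds
#'   the prominence threshold. Ties go to the earlier (warmer) sample.
#' @export
detect_nucleation <- function(tg, window = c(-12, -6), prominence = NULL,
                              median_k = 51) {
  stopifnot(inherits(tg, "thermogram"))
  window <- sort(window)
  idx <- which(tg$temperature_C >= window[1] & tg$temperature_C <= window[2])
  if (length(idx) < 3L) {
    message("no samples in the nucleation window")
    return(invisible(NULL))
  }
  # orient so spikes are negative excursions regardless of the convention
  sig <- tg$heat_flow_mW[idx] * (if (attr(tg, "exo_down")) 1 else -1)
  k <- min(median_k, length(sig) - (1 - length(sig) %% 2))
  if (k %% 2 == 0) k <- k - 1
  base <- if (k >= 3) stats::runmed(sig, k) else stats::median(sig)
  exc <- sig - base
  if (is.null(prominence))
    prominence <- max(10 * stats::median(abs(exc)), 1e-9)
  hits <- which(exc < -prominence)
  if (length(hits) == 0L) {
    message("no nucleation spike found (no excursion beyond the ",
            "prominence threshold)")
    return(invisible(NULL))
  }
  # most prominent excursion; exact ties go to the earlier (warmer) sample
  best <- hits[which(exc[hits] == min(exc[hits]))][1]
  list(index = idx[best], temperature_C = tg$temperature_C[idx[best]],
       excursion_mW = exc[best])
}

.new_baseline <- function(kind, idx, time, values, anchors_C, requested_C,
                          iterations = NA_integer_) {
  structure(list(kind = kind, index = idx, time_s = time, values = values,
                 anchors_C = anchors_C, requested_C = requested_C,
                 iterations = iterations),
            class = "dsc_baseline")
}

#' @export
print.dsc_baseline <- function(x, ...) {
  cat(sprintf(
    "<dsc_baseline> %s, anchors %.2f .. %.2f degC (%d samples)%s\n",
    x$kind, x$anchors_C[1], x$anchors_C[2], length(x$values),
    if (!is.na(x$iterations)) sprintf(", %d iterations", x$iterations)
    else ""))
  invisible(x)
}

#' Linear baseline between two anchor temperatures
#'
#' A straight line in time between the heat-flow values at the two anchor
#' temperatures: the phase-change temperature and (by convention) about
#' -40 degC. Anchors are matched to the nearest sampled temperatures and
#' the matched values are reported.
#'
#' @param tg A [thermogram()].
#' @param T_start Start anchor in degC; defaults to the phase-change
#'   temperature of the attached solution.
#' @param T_end End anchor in degC (default -40).
#' @return A `dsc_baseline` object aligned to the thermogram samples
#'   between the anchors.
#' @export
linear_baseline <- function(tg, T_start = NULL, T_end = -40) {
  stopifnot(inherits(tg, "thermogram"))
  T_start <- .default_Tstart(tg, T_start)
  a <- .anchor_indices(tg, T_start, T_end)
  idx <- a$i0:a$i1
  tt <- tg$time_s[idx]
  vals <- stats::approx(x = tg$time_s[c(a$i0, a$i1)],
                        y = tg$heat_flow_mW[c(a$i0, a$i1)],
                        xout = tt)$y
  .new_baseline("linear", idx, tt, vals,
                anchors_C = tg$temperature_C[c(a$i0, a$i1)],
                requested_C = c(T_start, T_end))
}

#' Iterative sigmoidal (partial-area) baseline
#'
#' The sigmoidal baseline interpolates between the extrapolated
#' pre-transition and post-transition linear trends, weighted by the
#' cumulative released fraction:
#' \deqn{b_i(t) = b_{pre}(t)\,(1 - \phi_{i-1}(t)) + b_{post}(t)\,\phi_{i-1}(t),}
#' where \eqn{\phi_{i-1}} is the running fraction of the exotherm area
#' computed against the previous iterate (seeded from the linear
#' baseline). Both trend lines are anchored to the signal value at their
#' anchor sample, so the baseline meets the signal at both ends. The
#' iteration stops when the largest pointwise change drops below
#' `tol` times the signal range between the anchors.
#'
#' @param tg A [thermogram()].
#' @param T_start Start anchor in degC; defaults to the solution's
#'   phase-change temperature.
#' @param T_end End anchor in degC (default -22, the usual sigmoidal
#'   convention).
#' @param max_iter Maximum iterations (default 50).
#' @param tol Relative convergence tolerance (default 1e-6 of the signal
#'   range).
#' @param trend_window_s Length of the windows (s) before/after the
#'   anchors used to estimate the pre-/post-transition slopes.
#' @return A `dsc_baseline` with `iterations` recorded.
#' @export
sigmoidal_baseline <- function(tg, T_start = NULL, T_end = -22,
                               max_iter = 50, tol = 1e-6,
                               trend_window_s = 30) {
  stopifnot(inherits(tg, "thermogram"))
  T_start <- .default_Tstart(tg, T_start)
  a <- .anchor_indices(tg, T_start, T_end)
  idx <- a$i0:a$i1
  tt <- tg$time_s[idx]
  sig <- tg$heat_flow_mW[idx]
  sgn <- .excess_sign(tg)

  # Theil-Sen (median of pairwise slopes): robust to the nucleation spike
  # or exotherm onset clipping the edge of a trend window
  trend_slope <- function(sel) {
    if (length(sel) < 2L)
      stop("too few samples to estimate a baseline trend (widen ",
           "`trend_window_s`)", call. = FALSE)
    x <- tg$time_s[sel]; y <- tg$heat_flow_mW[sel]
    dx <- outer(x, x, `-`)
    keep <- upper.tri(dx) & dx != 0
    stats::median((outer(y, y, `-`)[keep]) / dx[keep])
  }
  pre_sel <- which(tg$time_s >= tg$time_s[a$i0] - trend_window_s &
                     seq_along(tg$time_s) <= a$i0)
  post_sel <- which(tg$time_s <= tg$time_s[a$i1] + trend_window_s &
                      seq_along(tg$time_s) >= a$i1)
  b_pre <- sig[1] + trend_slope(pre_sel) * (tt - tt[1])
  b_post <- sig[length(sig)] +
    trend_slope(post_sel) * (tt - tt[length(tt)])

  scale <- diff(range(sig))
  if (scale == 0) scale <- max(abs(sig), 1)
  base <- stats::approx(tt[c(1, length(tt))], sig[c(1, length(sig))],
                        xout = tt)$y  # linear seed
  phi_from <- function(base) {
    cum <- .cumtrapz(tt, sgn * (base - sig))
    tot <- cum[length(cum)]
    if (tot <= 0)
      stop("non-positive exotherm area while building the sigmoidal ",
           "baseline", call. = FALSE)
    pmin(pmax(cum / tot, 0), 1)
  }
  iterations <- NA_integer_
  for (it in seq_len(max_iter)) {
    phi <- phi_from(base)
    base_new <- b_pre * (1 - phi) + b_post * phi
    delta <- max(abs(base_new - base))
    base <- base_new
    if (delta < tol * scale) { iterations <- it; break }
  }
  if (is.na(iterations))
    stop(sprintf(paste0("sigmoidal baseline did not converge in %d ",
                        "iterations (last change %.3g of signal scale)"),
                 max_iter, delta / scale), call. = FALSE)
  .new_baseline("sigmoidal", idx, tt, base,
                anchors_C = tg$temperature_C[c(a$i0, a$i1)],
                requested_C = c(T_start, T_end), iterations = iterations)
}

#' Integrate the latent heat under a thermogram
#'
#' Trapezoidal integral over time of the exothermic excess (baseline
#' minus signal under the exo-down convention) between the baseline
#' anchors, divided by the sample mass: mW.s/mg = mJ/mg.
#'
#' @param tg A [thermogram()].
#' @param baseline A `dsc_baseline` built from the same thermogram.
#' @return An object of class `dsc_integration`: list with
#'   `latent_heat_mJ_mg`, `baseline_kind`, `anchors_C`, `iterations` and
#'   `n_samples`.
#' @export
integrate_latent_heat <- function(tg, baseline) {
  stopifnot(inherits(tg, "thermogram"), inherits(baseline, "dsc_baseline"))
  idx <- baseline$index
  excess <- .excess_sign(tg) * (baseline$values - tg$heat_flow_mW[idx])
  total <- .trapz(baseline$time_s, excess)
  gross <- .trapz(baseline$time_s, abs(excess))
  if (total < -0.01 * gross - 1e-12 * max(abs(tg$heat_flow_mW)))
    stop("integrated exotherm is negative: check the sign convention ",
         "(`exo_down`)", call. = FALSE)
  structure(
    list(latent_heat_mJ_mg = total / attr(tg, "sample_mass_mg"),
         baseline_kind = baseline$kind,
         anchors_C = baseline$anchors_C,
         iterations = baseline$iterations,
         n_samples = length(idx)),
    class = "dsc_integration"
  )
}

#' @export
print.dsc_integration <- function(x, ...) {
  cat(sprintf(
    "<dsc_integration> %.2f mJ/mg (%s baseline, anchors %.2f .. %.2f degC)\n",
    x$latent_heat_mJ_mg, x$baseline_kind, x$anchors_C[1], x$anchors_C[2]))
  invisible(x)
}

#' Cumulative release curve from a thermogram
#'
#' Running time-integral of the exothermic excess between the baseline
#' anchors, normalised by the total, reported against temperature. The
#' final value is 1 by construction.
#'
#' @param tg A [thermogram()].
#' @param baseline A `dsc_baseline` built from the same thermogram.
#' @return A [release_curve()].
#' @export
cumulative_release_curve <- function(tg, baseline) {
  stopifnot(inherits(tg, "thermogram"), inherits(baseline, "dsc_baseline"))
  idx <- baseline$index
  excess <- .excess_sign(tg) * (baseline$values - tg$heat_flow_mW[idx])
  cum <- .cumtrapz(baseline$time_s, excess)
  total <- cum[length(cum)]
  if (total <= 0)
    stop("total exotherm area is not positive; cannot normalise",
         call. = FALSE)
  frac <- cum / total
  temp_K <- tg$temperature_C[idx] + 273.15
  # keep the strictly decreasing temperature subsequence (guards against
  # flat or jittery temperature samples at the window edges)
  running_min <- cummin(temp_K)
  keep <- temp_K < c(Inf, running_min[-length(running_min)])
  release_curve(temp_K[keep], frac[keep],
                cooling_rate = attr(tg, "cooling_rate"),
                solution = attr(tg, "solution"))
}
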