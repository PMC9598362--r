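#' @keywords internal
.rsq <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R^2 is undefined for constant data (zero total sum of squares)",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' R-squared of a model curve against a data curve
#'
#' Interpolates the model curve linearly in temperature onto the data
#' curve's grid and returns \eqn{1 - SS_{res}/SS_{tot}} with the total sum
#' of squares taken about the data mean. Can exceed no value above 1; it
#' is negative when the model does worse than the data mean.
#'
#' @param model A [release_curve()] holding model values.
#' @param data A [release_curve()] holding observations.
#' @return A single R-squared value.
#' @export
curve_r_squared <- function(model, data) {
  stopifnot(inherits(model, "release_curve"), inherits(data, "release_curve"))
  pred <- stats::approx(model$temperature, model$fraction,
                        xout = data$temperature, rule = 2)$y
  .rsq(data$fraction, pred)
}

#' Fit the temperature constant of the release model
#'
#' Least-squares fit of the one-parameter temperature function
#' \eqn{\alpha(T) = 1 - A/((T_{ph}-T)+A)} to one or more release curves.
#' Intended for the slowest cooling rate available (nominally 1 K/min),
#' where the kinetic lag is negligible and the measured fraction tracks
#' \eqn{\alpha} directly. Points at or above `Tph` are excluded.
#'
#' @param curves A [release_curve()] or list of them (replicates and/or
#'   curves from several solutions sharing `Tph`).
#' @param Tph Phase-change temperature (K).
#' @param A_init Starting value for the optimiser.
#' @param A_bounds Lower/upper bounds on `A` (K).
#' @return An object of class `avrami_fit_A`: list with `A`, `r_squared`
#'   (pooled), `n_points`, `sum_sq`, `Tph` and the optimiser `info`.
#' @export
fit_temperature_constant <- function(curves, Tph, A_init = 0.5,
                                     A_bounds = c(1e-6, 100)) {
  curves <- .as_curve_list(curves)
  temp <- unlist(lapply(curves, function(cv) cv$temperature))
  frac <- unlist(lapply(curves, function(cv) cv$fraction))
  keep <- temp < Tph
  temp <- temp[keep]; frac <- frac[keep]
  if (length(temp) < 2L)
    stop("fewer than 2 points below Tph", call. = FALSE)
  resid_fn <- function(par) frac - avrami_alpha(temp, par[["A"]], Tph)
  fit <- minpack.lm::nls.lm(
    par = c(A = A_init), fn = resid_fn,
    lower = A_bounds[1], upper = A_bounds[2],
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500))
  if (fit$info == 0 || fit$info == 5)
    stop("temperature-constant fit did not converge: ", fit$message,
         call. = FALSE)
  A_hat <- unname(fit$par[["A"]])
  structure(
    list(A = A_hat,
         r_squared = .rsq(frac, avrami_alpha(temp, A_hat, Tph)),
         n_points = length(temp),
         sum_sq = sum(resid_fn(c(A = A_hat))^2),
         Tph = Tph,
         info = list(status = fit$info, message = fit$message,
                     iterations = fit$niter)),
    class = "avrami_fit_A"
  )
}

#' @export
print.avrami_fit_A <- function(x, ...) {
  cat(sprintf("<avrami_fit_A> A = %.4f K (R^2 = %.4f, %d points)\n",
              x$A, x$r_squared, x$n_points))
  invisible(x)
}

.kn_pooled_resid <- function(par, curves, A, Tph, time_unit) {
  k <- par[["k"]]; n <- par[["n"]]
  unlist(lapply(curves, function(cv) {
    B <- attr(cv, "cooling_rate")
    below <- cv$temperature < Tph
    tt <- time_from_temperature(cv$temperature[below], Tph, B, time_unit)
    model <- avrami_alpha(cv$temperature[below], A, Tph) *
      avrami_beta(tt, k, n)
    cv$fraction[below] - model
  }))
}

#' Fit the Avrami kinetic parameters to one or more release curves
#'
#' Bounded nonlinear least squares for the rate constant `k` and time
#' exponent `n` of the composite model, with the temperature parameters
#' (`A`, `Tph`) held fixed (two-stage procedure: `A` comes from
#' [fit_temperature_constant()] on the slowest-rate data). In combined
#' mode (default) a single `(k, n)` pair minimises the squared residual
#' pooled over all supplied curves -- typically the 5 and 20 K/min curves
#' concurrently. With `combined = FALSE` each curve is fitted separately
#' and a list of fits is returned.
#'
#' The optimiser is Levenberg-Marquardt restarted from a coarse grid of
#' `(k, n)` values to avoid local minima; ties are broken by the lowest
#' pooled residual, then by the smallest `n`. Parameter estimates driven
#' to the box bounds are flagged in the report.
#'
#' @param curves A [release_curve()] or list of them.
#' @param A Temperature constant (K), fixed.
#' @param Tph Phase-change temperature (K), fixed.
#' @param time_unit Time unit `k` is expressed in; defaults to the first
#'   curve's convention.
#' @param combined Fit all curves with one `(k, n)` (default) or each
#'   curve separately.
#' @param k_bounds,n_bounds Box bounds for the two parameters.
#' @param k_starts,n_starts Coarse multi-start grids.
#' @return An object of class `avrami_fit_kn`: list with `k`, `n`, `A`,
#'   `Tph`, `time_unit`, `r_squared` (one value per curve, named by
#'   cooling rate), `sum_sq`, `at_bounds` and optimiser `info`. With
#'   `combined = FALSE`, a list of such objects.
#' @examples
#' p <- avrami_params(0.53, 3.3, 1.5, 272.62)
#' Tgrid <- seq(272.62, 232.62, length.out = 60)
#' curves <- lapply(c(5, 20), function(B)
#'   release_curve(Tgrid, latent_heat_fraction(Tgrid, p, B), B))
#' fit_kinetics(curves, A = 0.53, Tph = 272.62)
#' @export
fit_kinetics <- function(curves, A, Tph, time_unit = NULL, combined = TRUE,
                         k_bounds = c(1e-3, 1e3), n_bounds = c(0.05, 8),
                         k_starts = c(0.5, 1, 2, 4, 8),
                         n_starts = c(0.5, 1, 1.5, 2, 3)) {
  curves <- .as_curve_list(curves)
  if (is.null(time_unit)) time_unit <- attr(curves[[1]], "time_unit")
  if (!combined) {
    fits <- lapply(curves, fit_kinetics, A = A, Tph = Tph,
                   time_unit = time_unit, combined = TRUE,
                   k_bounds = k_bounds, n_bounds = n_bounds,
                   k_starts = k_starts, n_starts = n_starts)
    names(fits) <- vapply(curves, function(cv)
      paste0("B", attr(cv, "cooling_rate")), character(1))
    return(fits)
  }

  starts <- expand.grid(k = k_starts, n = n_starts)
  ss0 <- apply(starts, 1, function(p)
    sum(.kn_pooled_resid(c(k = p[["k"]], n = p[["n"]]), curves, A, Tph,
                         time_unit)^2))
  best_starts <- starts[order(ss0)[seq_len(min(3L, nrow(starts)))], ,
                        drop = FALSE]
  cands <- lapply(seq_len(nrow(best_starts)), function(i) {
    minpack.lm::nls.lm(
      par = c(k = best_starts$k[i], n = best_starts$n[i]),
      fn = .kn_pooled_resid, curves = curves, A = A, Tph = Tph,
      time_unit = time_unit,
      lower = c(k_bounds[1], n_bounds[1]),
      upper = c(k_bounds[2], n_bounds[2]),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500))
  })
  ok <- vapply(cands, function(f) !(f$info %in% c(0L, 5L)), logical(1))
  if (!any(ok))
    stop("kinetics fit did not converge from any start: ",
         cands[[1]]$message, call. = FALSE)
  cands <- cands[ok]
  ss <- vapply(cands, function(f) sum(f$fvec^2), numeric(1))
  nn <- vapply(cands, function(f) unname(f$par[["n"]]), numeric(1))
  # lowest pooled SS wins; ties (to within round-off) go to the smallest n
  best <- order(ss, nn)[1]
  fit <- cands[[best]]
  k_hat <- unname(fit$par[["k"]]); n_hat <- unname(fit$par[["n"]])

  at_bounds <- c(
    k = isTRUE(all.equal(k_hat, k_bounds[1])) ||
      isTRUE(all.equal(k_hat, k_bounds[2])),
    n = isTRUE(all.equal(n_hat, n_bounds[1])) ||
      isTRUE(all.equal(n_hat, n_bounds[2])))
  if (any(at_bounds))
    warning("fitted parameter(s) at box bounds: ",
            paste(names(at_bounds)[at_bounds], collapse = ", "))

  r2 <- vapply(curves, function(cv) {
    below <- cv$temperature < Tph
    tt <- time_from_temperature(cv$temperature[below], Tph,
                                attr(cv, "cooling_rate"), time_unit)
    model <- avrami_alpha(cv$temperature[below], A, Tph) *
      avrami_beta(tt, k_hat, n_hat)
    .rsq(cv$fraction[below], model)
  }, numeric(1))
  names(r2) <- vapply(curves, function(cv)
    paste0("B", attr(cv, "cooling_rate")), character(1))

  structure(
    list(k = k_hat, n = n_hat, A = A, Tph = Tph, time_unit = time_unit,
         r_squared = r2, sum_sq = sum(fit$fvec^2), at_bounds = at_bounds,
         info = list(status = fit$info, message = fit$message,
                     iterations = fit$niter)),
    class = "avrami_fit_kn"
  )
}

#' @export
print.avrami_fit_kn <- function(x, ...) {
  cat(sprintf("<avrami_fit_kn> k = %.4f %s^-%g, n = %.4f (A = %.3f fixed)\n",
              x$k, substr(x$time_unit, 1, 3), x$n, x$n, x$A))
  cat("  per-curve R^2:",
      paste(sprintf("%s = %.4f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

#' Goodness-of-fit surface over the (k, n) plane
#'
#' Evaluates the per-curve R-squared of the composite model on a
#' rectangular grid of `(k, n)` values (with `A` and `Tph` fixed), plus a
#' mask of the region where every curve reaches the threshold. The
#' combined best fit is expected to lie inside the intersection of the
#' per-rate regions.
#'
#' @param curves A [release_curve()] or list of them.
#' @param A,Tph Fixed temperature parameters.
#' @param k_grid,n_grid Grid values for the rate constant and exponent.
#' @param threshold Goodness-of-fit threshold for the mask (default 0.95).
#' @param time_unit Time unit; defaults to the first curve's convention.
#' @return An object of class `r2_surface`: list with `k`, `n`, `r2` (a
#'   list of `length(k) x length(n)` matrices, one per curve, named by
#'   cooling rate), `mask_each` (per-curve logical matrices at the
#'   threshold), `mask` (their intersection; all-`FALSE` when the region
#'   is empty) and `threshold`.
#' @export
r2_surface <- function(curves, A, Tph, k_grid, n_grid, threshold = 0.95,
                       time_unit = NULL) {
  curves <- .as_curve_list(curves)
  if (is.null(time_unit)) time_unit <- attr(curves[[1]], "time_unit")
  r2 <- lapply(curves, function(cv) {
    B <- attr(cv, "cooling_rate")
    below <- cv$temperature < Tph
    tt <- time_from_temperature(cv$temperature[below], Tph, B, time_unit)
    a <- avrami_alpha(cv$temperature[below], A, Tph)
    obs <- cv$fraction[below]
    m <- matrix(NA_real_, length(k_grid), length(n_grid),
                dimnames = list(k = signif(k_grid, 6),
                                n = signif(n_grid, 6)))
    for (i in seq_along(k_grid))
      for (j in seq_along(n_grid))
        m[i, j] <- .rsq(obs, a * avrami_beta(tt, k_grid[i], n_grid[j]))
    m
  })
  names(r2) <- vapply(curves, function(cv)
    paste0("B", attr(cv, "cooling_rate")), character(1))
  mask_each <- lapply(r2, function(m) m >= threshold)
  mask <- Reduce(`&`, mask_each)
  structure(list(k = k_grid, n = n_grid, r2 = r2, mask_each = mask_each,
                 mask = mask, threshold = threshold),
            class = "r2_surface")
}

#' @export
print.r2_surface <- function(x, ...) {
  cat(sprintf(
    "<r2_surface> %d x %d (k, n) grid, %d curve(s); %d node(s) with all ",
    length(x$k), length(x$n), length(x$r2), sum(x$mask)))
  cat(sprintf("R^2 >= %.2f\n", x$threshold))
  invisible(x)
}
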