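#' Physical parameters of the moving-boundary freezing model
#'
#' Collects the physical constants of the reduced heat- and
#' mass-transfer-limited model of a salt solution freezing in a small
#' cylindrical container (a DSC pan) under an imposed constant cooling
#' rate. The container radius and dendrite thickness are carried for
#' provenance; the reduced model is one-dimensional in the fill height
#' and does not use them.
#'
#' @param cooling_rate Cooling rate B in K/min.
#' @param height Solution fill height H in m (default 5e-4).
#' @param osmolality Initial solute concentration c0 in Osm/L (default
#'   0.2853, isotonic PBS).
#' @param slope Freezing-point depression slope m in K/(Osm/L).
#' @param latent_heat Latent heat of fusion L in J/g (default 335).
#' @param heat_capacity Liquid heat capacity c_l in J/(g.K) (default
#'   4.18, water).
#' @param k_ice,k_liquid Thermal conductivities in W/(m.K); only their
#'   ratio enters the dimensionless bookkeeping.
#' @param D_T_ice,D_T_liquid Thermal diffusivities in m^2/s.
#' @param stokes_einstein Stokes-Einstein prefactor k_B/(6 pi R_h) in
#'   m^2.cP/(K.min) (default 9.17e-14), so that the solute diffusivity is
#'   `stokes_einstein * T / viscosity(T)` in m^2/min.
#' @param visc_prefactor,visc_activation,gas_constant Arrhenius viscosity
#'   model constants: mu(T) = visc_prefactor * exp(visc_activation /
#'   (gas_constant * T)) in cP.
#' @param radius Container radius in m (default 2e-3).
#' @param dendrite_thickness Mean dendrite finger thickness in m
#'   (default 5e-5).
#' @return An object of class `stefan_params` with the derived
#'   phase-change temperature `Tph`.
#' @export
stefan_params <- function(cooling_rate, height = 5e-4, osmolality = 0.2853,
                          slope = 1.858, latent_heat = 335,
                          heat_capacity = 4.18, k_ice = 2.22,
                          k_liquid = 0.556, D_T_ice = 1.1e-6,
                          D_T_liquid = 1.3e-7, stokes_einstein = 9.17e-14,
                          visc_prefactor = 6.627e-4,
                          visc_activation = 1.807e4, gas_constant = 8.314,
                          radius = 2e-3, dendrite_thickness = 5e-5) {
  p <- list(cooling_rate = cooling_rate, height = height,
            osmolality = osmolality, slope = slope,
            latent_heat = latent_heat, heat_capacity = heat_capacity,
            k_ice = k_ice, k_liquid = k_liquid, D_T_ice = D_T_ice,
            D_T_liquid = D_T_liquid, stokes_einstein = stokes_einstein,
            visc_prefactor = visc_prefactor,
            visc_activation = visc_activation, gas_constant = gas_constant,
            radius = radius, dendrite_thickness = dendrite_thickness)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("parameters must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  p$Tph <- 273.15 - slope * osmolality
  structure(p, class = "stefan_params")
}

#' @export
print.stefan_params <- function(x, ...) {
  cat(sprintf(
    "<stefan_params> B = %g K/min, H = %g m, c0 = %g Osm/L, Tph = %.2f K\n",
    x$cooling_rate, x$height, x$osmolality, x$Tph))
  invisible(x)
}

#' Dimensionless groups of the freezing model
#'
#' Non-dimensionalising the two-phase conduction/diffusion system with
#' length scale H and time scale Tph/B gives: inverse thermal
#' diffusivities \eqn{\epsilon_i = B H^2/(T_{ph} D_{T,i})}, inverse
#' compositional diffusivity \eqn{\gamma^2 = B H^2/(T_{ph} D_c)}, the
#' Stefan number \eqn{St = L/(T_{ph} c_l)}, the concentration scale
#' \eqn{M = m c_0 / T_{ph}} and the conductivity ratio \eqn{k_1/k_2}.
#' Diffusivities are converted to per-minute units so every group is
#' dimensionless with B in K/min. \eqn{\epsilon_i} is tiny for any
#' realistic cooling rate, which justifies the quasi-steady thermal field
#' of the reduced model; \eqn{\gamma^2} is not, which is why the solute
#' field lags and the latent heat release depends on the cooling rate.
#'
#' @param p A [stefan_params()].
#' @return An object of class `dimensionless_groups`: list with
#'   `epsilon_ice`, `epsilon_liquid`, `gamma2` (at T = Tph),
#'   `stefan_number`, `M` and `k_ratio`.
#' @export
dimensionless_groups <- function(p) {
  stopifnot(inherits(p, "stefan_params"))
  f <- p$cooling_rate * p$height^2 / p$Tph
  structure(
    list(epsilon_ice = f / (p$D_T_ice * 60),
         epsilon_liquid = f / (p$D_T_liquid * 60),
         gamma2 = gamma2_at(0, p),
         stefan_number = p$latent_heat / (p$Tph * p$heat_capacity),
         M = p$slope * p$osmolality / p$Tph,
         k_ratio = p$k_ice / p$k_liquid),
    class = "dimensionless_groups"
  )
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf(
    paste0("<dimensionless_groups> eps_ice = %.3g, eps_liq = %.3g, ",
           "gamma2 = %.3g, St = %.3g, M = %.3g, k1/k2 = %.3g\n"),
    x$epsilon_ice, x$epsilon_liquid, x$gamma2, x$stefan_number, x$M,
    x$k_ratio))
  invisible(x)
}

#' Arrhenius viscosity of water
#'
#' \eqn{\mu(T) = A e^{F/(R T)}} in centipoise; about 1 cP at 298 K and
#' rising steeply as the solution cools.
#'
#' @param temperature Temperature(s) in kelvin, positive.
#' @param prefactor,activation,gas_constant Model constants (defaults
#'   6.627e-4 cP, 1.807e4, 8.314).
#' @return Viscosity in cP.
#' @examples
#' water_viscosity(298)  # ~0.97 cP
#' @export
water_viscosity <- function(temperature, prefactor = 6.627e-4,
                            activation = 1.807e4, gas_constant = 8.314) {
  if (any(temperature <= 0))
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  prefactor * exp(activation / (gas_constant * temperature))
}

#' Stokes-Einstein solute diffusivity
#'
#' \eqn{D_c(T) = S \cdot T / \mu(T)} in m^2/min, with the Stokes-Einstein
#' prefactor S and the Arrhenius viscosity of [water_viscosity()].
#' Monotonically increasing in temperature: colder solutions are more
#' viscous and diffuse solute more slowly.
#'
#' @param temperature Temperature(s) in kelvin, positive.
#' @param stokes_einstein Prefactor S in m^2.cP/(K.min) (default 9.17e-14).
#' @param ... Passed to [water_viscosity()].
#' @return Diffusivity in m^2/min.
#' @export
solute_diffusivity <- function(temperature, stokes_einstein = 9.17e-14,
                               ...) {
  stokes_einstein * temperature / water_viscosity(temperature, ...)
}

#' Inverse compositional diffusivity along a cooling run
#'
#' \eqn{\gamma^2(t) = B H^2 / (T_{ph} D_c(T(t)))} with the quasi-steady
#' uniform liquid temperature \eqn{T(t) = T_{ph}(1 - t)} (t is
#' non-dimensional time). In `"constant"` mode the value at t = 0 is
#' returned for all t (the order-of-magnitude convention).
#'
#' @param t Non-dimensional time(s), `t < 1`.
#' @param p A [stefan_params()].
#' @param mode `"temperature"` (default; evaluate the diffusivity at the
#'   current liquid temperature) or `"constant"`.
#' @param scale Multiplier applied to the result (used to probe the
#'   fast-diffusion, quasi-equilibrium limit).
#' @return Dimensionless gamma^2 value(s).
#' @export
gamma2_at <- function(t, p, mode = c("temperature", "constant"),
                      scale = 1) {
  stopifnot(inherits(p, "stefan_params"))
  mode <- match.arg(mode)
  if (mode == "constant") t <- rep(0, length(t))
  temp <- p$Tph * (1 - t)
  if (any(temp <= 0))
    stop("liquid temperature T(t) = Tph(1 - t) must stay positive",
         call. = FALSE)
  Dc <- solute_diffusivity(temp, p$stokes_einstein,
                           prefactor = p$visc_prefactor,
                           activation = p$visc_activation,
                           gas_constant = p$gas_constant)
  scale * p$cooling_rate * p$height^2 / (p$Tph * Dc)
}
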