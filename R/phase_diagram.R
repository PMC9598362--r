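#' Describe a solute-laden aqueous solution
#'
#' A solution is characterised by its osmolality and the freezing-point
#' depression slope of the water--NaCl binary phase diagram. The
#' phase-change temperature is derived as
#' \eqn{T_{ph} = 273.15 - m \cdot c_0} (kelvin).
#'
#' @param name Label for the solution (e.g. `"1xPBS"`).
#' @param osmolality Osmolality \eqn{c_0} in Osm/L. Must be non-negative.
#' @param slope Freezing-point depression slope \eqn{m} in K per Osm/L;
#'   the dilute-solution value for water--NaCl is 1.858.
#'
#' @return An object of class `solution_spec`: a list with elements
#'   `name`, `osmolality`, `slope` and the derived `Tph` (K).
#' @examples
#' pbs <- solution_spec("1xPBS", 0.2853)
#' pbs$Tph  # 272.62 K
#' @export
solution_spec <- function(name, osmolality, slope = 1.858) {
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single string", call. = FALSE)
  if (!is.numeric(osmolality) || length(osmolality) != 1L ||
      !is.finite(osmolality) || osmolality < 0)
    stop("`osmolality` must be a single non-negative number (Osm/L)",
         call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("`slope` must be a single positive number (K per Osm/L)",
         call. = FALSE)
  structure(
    list(name = name, osmolality = osmolality, slope = slope,
         Tph = 273.15 - slope * osmolality),
    class = "solution_spec"
  )
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> %s\n", x$name))
  cat(sprintf("  osmolality: %.4f Osm/L  (m = %.3f K/(Osm/L))\n",
              x$osmolality, x$slope))
  cat(sprintf("  phase-change temperature: %.2f K (%.2f degC)\n",
              x$Tph, x$Tph - 273.15))
  invisible(x)
}

#' Phase-change temperature from osmolality
#'
#' Freezing-point depression for a dilute aqueous solution:
#' \eqn{T_{ph} = 273.15 - m \cdot c_0}.
#'
#' @param osmolality Osmolality in Osm/L (vectorised, non-negative).
#' @param slope Depression slope in K per Osm/L (default 1.858).
#' @return Phase-change temperature(s) in kelvin.
#' @examples
#' phase_change_temperature(0)       # 273.15 (pure water)
#' phase_change_temperature(0.2853)  # 272.62 (isotonic PBS)
#' @export
phase_change_temperature <- function(osmolality, slope = 1.858) {
  if (!is.numeric(osmolality) || any(!is.finite(osmolality)) ||
      any(osmolality < 0))
    stop("`osmolality` must be non-negative and finite", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("`slope` must be a single positive number", call. = FALSE)
  273.15 - slope * osmolality
}

#' Liquidus osmolality at a temperature
#'
#' Inverse of [phase_change_temperature()]: the osmolality of the residual
#' liquid sitting on the liquidus at temperature `temperature`.
#'
#' @param temperature Temperature in kelvin, at or below 273.15.
#' @param slope Depression slope in K per Osm/L.
#' @return Osmolality in Osm/L.
#' @export
liquidus_osmolality <- function(temperature, slope = 1.858) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)))
    stop("`temperature` must be finite", call. = FALSE)
  if (any(temperature > 273.15))
    stop("`temperature` must not exceed 273.15 K (no liquidus above the ",
         "pure-water melting point)", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("`slope` must be a single positive number", call. = FALSE)
  (273.15 - temperature) / slope
}

#' Equilibrium (lever-rule) latent-heat release fraction
#'
#' Fraction of the freezable water that has crystallised when the residual
#' liquid is in equilibrium on the liquidus at temperature `temperature`:
#' \deqn{f(T) = 1 - \frac{m c_0}{273.15 - T}, \quad T < T_{ph},}
#' and 0 at or above \eqn{T_{ph}}. This is the release profile defined by
#' the binary phase diagram, used as the slow-cooling (quasi-equilibrium)
#' reference curve. For pure water (`osmolality == 0`) the fraction is a
#' step: 0 at or above 273.15 K, 1 below (all heat released at the melting
#' point); this limiting case is returned rather than raising an error.
#'
#' @param temperature Temperature(s) in kelvin.
#' @param spec A [solution_spec()].
#' @return Release fraction(s) in `[0, 1)` (`[0, 1]` for pure water).
#' @examples
#' pbs <- solution_spec("1xPBS", 0.2853)
#' equilibrium_release_fraction(263.15, pbs)  # 0.947
#' @export
equilibrium_release_fraction <- function(temperature, spec) {
  stopifnot(inherits(spec, "solution_spec"))
  if (!is.numeric(temperature) || any(!is.finite(temperature)))
    stop("`temperature` must be finite", call. = FALSE)
  mc0 <- spec$slope * spec$osmolality
  if (mc0 == 0) return(as.numeric(temperature < 273.15))
  ifelse(temperature >= spec$Tph, 0, 1 - mc0 / (273.15 - temperature))
}

#' Built-in solution presets
#'
#' Reads the solution presets shipped with the package (or any file in the
#' same JSON format: an array of objects with fields `name`,
#' `osmolality_osm` and `m_K_per_osm`).
#'
#' Two presets exist for isotonic PBS: `"1xPBS"` (0.2853 Osm/L, the value
#' consistent with a fitted temperature constant of 0.53 K and a
#' phase-change temperature of 272.62 K) and `"1xPBS_nominal"`
#' (0.3 Osm/L, the nominal osmolality of 0.9 wt% NaCl, giving 272.59 K).
#' The 0.03 K difference between the two conventions is real and is left
#' to the user's choice; `"1xPBS"` is the default used throughout.
#'
#' @param path Path to a presets JSON file; defaults to the installed copy.
#' @return A named list of [solution_spec()] objects.
#' @export
solution_presets <- function(path = system.file("extdata", "solutions.json",
                                                package = "icecal")) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(x) {
    solution_spec(x$name, x$osmolality_osm, x$m_K_per_osm)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Export solution specs (with derived phase-change temperatures) to JSON
#'
#' @param specs A list of [solution_spec()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_solutions <- function(specs, path) {
  if (inherits(specs, "solution_spec")) specs <- list(specs)
  out <- lapply(specs, function(s) {
    list(name = s$name, osmolality_osm = s$osmolality,
         m_K_per_osm = s$slope, Tph_K = s$Tph)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
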