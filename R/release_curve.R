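#' Cumulative latent-heat release curve
#'
#' A release curve records the cumulative fraction of latent heat released
#' as a function of temperature while a sample is cooled at a constant
#' rate. Temperatures must be strictly decreasing along the record (the
#' direction of a cooling run). Fractions from noiseless models are
#' non-decreasing as temperature falls; measured or noisy fractions may
#' wobble, so monotonicity is not enforced here.
#'
#' @param temperature Temperatures in kelvin, strictly decreasing.
#' @param fraction Release fractions, same length as `temperature`.
#' @param cooling_rate Cooling rate B in K/min (positive).
#' @param replicate Optional replicate identifier.
#' @param solution Optional [solution_spec()] the curve belongs to.
#' @param time_unit Time unit convention carried with the curve
#'   (`"minutes"` or `"seconds"`), used when kinetics are fitted to it.
#'
#' @return A data frame of class `release_curve` with columns
#'   `temperature` (K) and `fraction`, and attributes `cooling_rate`,
#'   `replicate`, `solution` and `time_unit`.
#' @export
release_curve <- function(temperature, fraction, cooling_rate,
                          replicate = NA, solution = NULL,
                          time_unit = c("minutes", "seconds")) {
  time_unit <- match.arg(time_unit)
  if (!is.numeric(temperature) || !is.numeric(fraction) ||
      length(temperature) != length(fraction))
    stop("`temperature` and `fraction` must be numeric vectors of equal ",
         "length", call. = FALSE)
  if (length(temperature) < 2L)
    stop("a release curve needs at least two samples", call. = FALSE)
  if (any(!is.finite(temperature)) || any(!is.finite(fraction)))
    stop("`temperature` and `fraction` must be finite", call. = FALSE)
  if (any(diff(temperature) >= 0))
    stop("`temperature` must be strictly decreasing (cooling direction)",
         call. = FALSE)
  if (!is.numeric(cooling_rate) || length(cooling_rate) != 1L ||
      cooling_rate <= 0)
    stop("`cooling_rate` must be a single positive number (K/min)",
         call. = FALSE)
  if (any(fraction < -0.05) || any(fraction > 1.05))
    warning("release fractions outside [-0.05, 1.05]; check the data")
  if (!is.null(solution)) stopifnot(inherits(solution, "solution_spec"))
  structure(
    data.frame(temperature = temperature, fraction = fraction),
    cooling_rate = cooling_rate,
    replicate = replicate,
    solution = solution,
    time_unit = time_unit,
    class = c("release_curve", "data.frame")
  )
}

#' @export
print.release_curve <- function(x, ...) {
  sol <- attr(x, "solution")
  cat(sprintf(
    "<release_curve> %d samples, B = %g K/min%s\n", nrow(x),
    attr(x, "cooling_rate"),
    if (!is.null(sol)) paste0(", solution ", sol$name) else ""))
  cat(sprintf("  temperature %.2f .. %.2f K, fraction %.4f .. %.4f\n",
              x$temperature[1], x$temperature[nrow(x)],
              x$fraction[1], x$fraction[nrow(x)]))
  invisible(x)
}

.as_curve_list <- function(curves) {
  if (inherits(curves, "release_curve")) return(list(curves))
  if (!is.list(curves) || !all(vapply(curves, inherits, logical(1),
                                      "release_curve")))
    stop("expected a release_curve or a list of release_curve objects",
         call. = FALSE)
  curves
}

#' Read / write release curves as CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `temperature_K` (or `temperature_C`, detected
#' from the header and converted), `fraction` and optionally `replicate`.
#' Metadata (`cooling_rate_K_min`, `time_unit`, and the solution's `name`,
#' `osmolality_osm`, `m_K_per_osm`) live in a sidecar JSON file at
#' `<path>.json`.
#'
#' @param path CSV path.
#' @return `read_release_curves()` returns a list of [release_curve()]
#'   objects (one per replicate). `write_release_curves()` returns `path`
#'   invisibly.
#' @export
read_release_curves <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if ("temperature_C" %in% names(df)) {
    temp <- df$temperature_C + 273.15
  } else if ("temperature_K" %in% names(df)) {
    temp <- df$temperature_K
  } else {
    stop("no temperature_K or temperature_C column in ", path, call. = FALSE)
  }
  if (!"fraction" %in% names(df))
    stop("no fraction column in ", path, call. = FALSE)
  rep_id <- if ("replicate" %in% names(df)) df$replicate else rep(1L, nrow(df))
  sol <- NULL
  if (!is.null(meta$solution))
    sol <- solution_spec(meta$solution$name, meta$solution$osmolality_osm,
                         meta$solution$m_K_per_osm)
  tu <- if (!is.null(meta$time_unit)) meta$time_unit else "minutes"
  lapply(split(seq_len(nrow(df)), rep_id), function(i) {
    release_curve(temp[i], df$fraction[i],
                  cooling_rate = as.numeric(meta$cooling_rate_K_min),
                  replicate = rep_id[i[1]], solution = sol, time_unit = tu)
  })
}

#' @rdname read_release_curves
#' @param curves A [release_curve()] or list of them (replicates of one
#'   cooling rate).
#' @export
write_release_curves <- function(curves, path) {
  curves <- .as_curve_list(curves)
  rate <- attr(curves[[1]], "cooling_rate")
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    rep_id <- attr(cv, "replicate")
    if (is.na(rep_id)) rep_id <- i
    data.frame(temperature_K = cv$temperature, fraction = cv$fraction,
               replicate = rep_id)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sol <- attr(curves[[1]], "solution")
  meta <- list(cooling_rate_K_min = rate,
               time_unit = attr(curves[[1]], "time_unit"))
  if (!is.null(sol))
    meta$solution <- list(name = sol$name, osmolality_osm = sol$osmolality,
                          m_K_per_osm = sol$slope)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
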