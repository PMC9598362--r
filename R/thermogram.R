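#' DSC thermogram container
#'
#' A thermogram is the sampled record of a differential scanning
#' calorimetry run: time (s), sample temperature (degC) and heat flow
#' (mW), together with the sample mass and the programmed cooling rate.
#' Under the default sign convention (`exo_down = TRUE`) exothermic events
#' -- the nucleation spike and the freezing exotherm -- appear as negative
#' heat-flow excursions.
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param temperature_C Sample temperature in degrees Celsius.
#' @param heat_flow_mW Heat flow in mW.
#' @param sample_mass_mg Sample mass in mg, positive.
#' @param cooling_rate Programmed cooling rate B in K/min.
#' @param solution Optional [solution_spec()].
#' @param exo_down Logical; `TRUE` (default) when exotherms are negative.
#' @return A data frame of class `thermogram` with the three signal
#'   columns and metadata attributes.
#' @export
thermogram <- function(time_s, temperature_C, heat_flow_mW, sample_mass_mg,
                       cooling_rate, solution = NULL, exo_down = TRUE) {
  if (!is.numeric(time_s) || !is.numeric(temperature_C) ||
      !is.numeric(heat_flow_mW))
    stop("time_s, temperature_C and heat_flow_mW must be numeric",
         call. = FALSE)
  n <- length(time_s)
  if (length(temperature_C) != n || length(heat_flow_mW) != n)
    stop("signal columns must have equal length", call. = FALSE)
  if (n < 2L) stop("a thermogram needs at least two samples", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (!is.numeric(sample_mass_mg) || length(sample_mass_mg) != 1L ||
      !is.finite(sample_mass_mg) || sample_mass_mg <= 0)
    stop("sample_mass_mg must be a single positive number", call. = FALSE)
  if (!is.numeric(cooling_rate) || length(cooling_rate) != 1L ||
      cooling_rate <= 0)
    stop("cooling_rate must be a single positive number (K/min)",
         call. = FALSE)
  if (!is.null(solution)) stopifnot(inherits(solution, "solution_spec"))
  structure(
    data.frame(time_s = time_s, temperature_C = temperature_C,
               heat_flow_mW = heat_flow_mW),
    sample_mass_mg = sample_mass_mg,
    cooling_rate = cooling_rate,
    solution = solution,
    exo_down = isTRUE(exo_down),
    class = c("thermogram", "data.frame")
  )
}

#' @export
print.thermogram <- function(x, ...) {
  sol <- attr(x, "solution")
  cat(sprintf(
    "<thermogram> %d samples over %.1f s, mass %.2f mg, B = %g K/min%s\n",
    nrow(x), x$time_s[nrow(x)] - x$time_s[1], attr(x, "sample_mass_mg"),
    attr(x, "cooling_rate"),
    if (!is.null(sol)) paste0(", solution ", sol$name) else ""))
  cat(sprintf("  temperature %.2f .. %.2f degC, heat flow %.3f .. %.3f mW",
              max(x$temperature_C), min(x$temperature_C),
              min(x$heat_flow_mW), max(x$heat_flow_mW)))
  cat(if (attr(x, "exo_down")) "  (exo down)\n" else "  (exo up)\n")
  invisible(x)
}

#' Read and write thermograms as annotated CSV
#'
#' The on-disk format is a plain CSV with a block of `# key: value`
#' header comments carrying the metadata, followed by columns `time_s`,
#' `temperature_C` (or `temperature_K`, detected from the header and
#' converted) and `heat_flow_mW`. Values are written at full double
#' precision, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return `read_thermogram()` returns a [thermogram()];
#'   `write_thermogram()` returns `path` invisibly.
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  if (!"time_s" %in% names(df))
    stop("missing column time_s in ", path, call. = FALSE)
  if ("temperature_K" %in% names(df)) {
    df$temperature_C <- df$temperature_K - 273.15
  } else if (!"temperature_C" %in% names(df)) {
    stop("missing column temperature_C (or temperature_K) in ", path,
         call. = FALSE)
  }
  if (!"heat_flow_mW" %in% names(df))
    stop("missing column heat_flow_mW in ", path, call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time axis in ", path, call. = FALSE)
  if (is.null(meta$sample_mass_mg))
    stop("missing sample_mass_mg metadata in ", path, call. = FALSE)
  if (is.null(meta$cooling_rate_K_min))
    stop("missing cooling_rate_K_min metadata in ", path, call. = FALSE)
  sol <- NULL
  if (!is.null(meta$solution_name))
    sol <- solution_spec(meta$solution_name,
                         as.numeric(meta$solution_osmolality_osm),
                         as.numeric(meta$solution_m_K_per_osm))
  thermogram(df$time_s, df$temperature_C, df$heat_flow_mW,
             sample_mass_mg = as.numeric(meta$sample_mass_mg),
             cooling_rate = as.numeric(meta$cooling_rate_K_min),
             solution = sol,
             exo_down = is.null(meta$exo_down) ||
               identical(toupper(meta$exo_down), "TRUE"))
}

#' @rdname read_thermogram
#' @param tg A [thermogram()].
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  sol <- attr(tg, "solution")
  hdr <- c(
    "# icecal thermogram v1",
    sprintf("# sample_mass_mg: %.17g", attr(tg, "sample_mass_mg")),
    sprintf("# cooling_rate_K_min: %.17g", attr(tg, "cooling_rate")),
    sprintf("# exo_down: %s", attr(tg, "exo_down")))
  if (!is.null(sol))
    hdr <- c(hdr,
             sprintf("# solution_name: %s", sol$name),
             sprintf("# solution_osmolality_osm: %.17g", sol$osmolality),
             sprintf("# solution_m_K_per_osm: %.17g", sol$slope))
  body <- sprintf("%.17g,%.17g,%.17g", tg$time_s, tg$temperature_C,
                  tg$heat_flow_mW)
  writeLines(c(hdr, "time_s,temperature_C,heat_flow_mW", body), path)
  invisible(path)
}
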