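# Run orchestration: YAML-configured workflows tying the modules together,
# with deterministic artifacts, seed logging and overwrite protection.

.guard_write <- function(path, overwrite) {
  if (file.exists(path) && !isTRUE(overwrite))
    stop("refusing to overwrite ", path,
         " (set overwrite: true in the config)", call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  path
}

.cfg_get <- function(cfg, key, default = NULL, required = FALSE) {
  v <- cfg[[key]]
  if (is.null(v)) {
    if (required)
      stop("config field `", key, "` is required", call. = FALSE)
    return(default)
  }
  v
}

.cfg_solution <- function(cfg) {
  s <- .cfg_get(cfg, "solution", required = TRUE)
  if (is.character(s) && length(s) == 1L) {
    presets <- solution_presets()
    if (!s %in% names(presets))
      stop("unknown solution preset `", s, "`; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    return(presets[[s]])
  }
  solution_spec(s$name, s$osmolality, .cfg_get(s, "slope", 1.858))
}

.cfg_model <- function(cfg, solution) {
  m <- .cfg_get(cfg, "model", list(type = "equilibrium"))
  if (identical(m$type, "equilibrium")) return("equilibrium")
  if (identical(m$type, "avrami"))
    return(avrami_params(m$A, m$k, m$n,
                         Tph = .cfg_get(m, "Tph", solution$Tph),
                         time_unit = .cfg_get(m, "time_unit", "minutes")))
  if (identical(m$type, "stefan"))
    return(stefan_params(cooling_rate = m$cooling_rate,
                         height = .cfg_get(m, "height", 5e-4),
                         osmolality = solution$osmolality,
                         slope = solution$slope))
  stop("unknown model type `", m$type, "`", call. = FALSE)
}

#' Read a run configuration
#'
#' Run configurations are YAML (or JSON) mappings with a required
#' `out_dir`, an optional `seed` and `overwrite` flag, and one section
#' per workflow (`synth`, `integrate`, `fit`, `simulate`, `compare`).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$out_dir))
    stop("config field `out_dir` is required", call. = FALSE)
  structure(cfg, class = "run_config")
}

.write_manifest <- function(cfg, out_dir, what, files) {
  manifest <- list(
    workflow = what,
    package_version = as.character(utils::packageVersion("icecal")),
    seed = .cfg_get(cfg, "seed", NA),
    files = files)
  path <- file.path(out_dir, paste0(what, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  path
}

#' Workflow runners
#'
#' Each runner executes one configured workflow and writes a
#' deterministic artifact set (CSV data, JSON reports, a manifest
#' recording the seed and package version) under the config's `out_dir`.
#' Existing artifacts are never overwritten unless the config sets
#' `overwrite: true`. Reruns with the same config and seed produce
#' byte-identical JSON artifacts.
#'
#' * `run_synth()`: generate release curves (and optionally thermograms)
#'   for each configured cooling rate.
#' * `run_integrate()`: read thermogram CSVs, build linear and sigmoidal
#'   baselines, integrate the latent heat and export cumulative curves.
#' * `run_fit()`: two-stage model fit -- temperature constant on the
#'   slowest-rate curves, then the combined kinetics fit on the rest.
#' * `run_simulate()`: moving-boundary simulations across cooling rates.
#' * `run_compare()`: overlay model against data curves, reporting
#'   sup-norm deviations and R-squared per rate.
#'
#' @param cfg A [read_run_config()] object (or a path to one).
#' @return A named list of artifact paths, invisibly.
#' @name pipeline
NULL

.as_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  cfg
}

#' @rdname pipeline
#' @export
run_synth <- function(cfg) {
  cfg <- .as_config(cfg)
  sc <- .cfg_get(cfg, "synth", required = TRUE)
  out_dir <- cfg$out_dir
  overwrite <- isTRUE(cfg$overwrite)
  sol <- .cfg_solution(sc)
  model <- .cfg_model(sc, sol)
  rates <- .cfg_get(sc, "cooling_rates", required = TRUE)
  seed <- .cfg_get(cfg, "seed", 1L)
  files <- character(0)
  for (i in seq_along(rates)) {
    B <- rates[[i]]
    model_B <- model
    if (inherits(model, "stefan_params")) model_B$cooling_rate <- B
    sp <- synth_spec(
      sol, cooling_rate = B, model = model_B,
      noise_fraction = .cfg_get(sc, "noise_fraction", 0),
      noise_mW = .cfg_get(sc, "noise_mW", 0),
      replicates = .cfg_get(sc, "replicates", 1),
      n_points = .cfg_get(sc, "n_points", 100),
      seed = seed + i)
    curves <- generate_release_curves(sp)
    path <- .guard_write(file.path(out_dir, sprintf("curves_B%g.csv", B)),
                         overwrite)
    write_release_curves(curves, path)
    files <- c(files, path)
    if (isTRUE(.cfg_get(sc, "thermograms", FALSE))) {
      tg <- generate_thermogram(sp)
      tpath <- .guard_write(
        file.path(out_dir, sprintf("thermogram_B%g.csv", B)), overwrite)
      write_thermogram(tg, tpath)
      files <- c(files, tpath)
    }
  }
  manifest <- .write_manifest(cfg, out_dir, "synth", files)
  invisible(list(files = files, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_integrate <- function(cfg) {
  cfg <- .as_config(cfg)
  ic <- .cfg_get(cfg, "integrate", required = TRUE)
  out_dir <- cfg$out_dir
  overwrite <- isTRUE(cfg$overwrite)
  paths <- .cfg_get(ic, "thermograms", required = TRUE)
  reports <- list()
  files <- character(0)
  for (path in paths) {
    tg <- read_thermogram(path)
    lin <- linear_baseline(tg, T_end = .cfg_get(ic, "linear_end_C", -40))
    sig <- sigmoidal_baseline(tg, T_end = .cfg_get(ic, "sigmoidal_end_C",
                                                   -22))
    int_lin <- integrate_latent_heat(tg, lin)
    int_sig <- integrate_latent_heat(tg, sig)
    curve <- cumulative_release_curve(tg, lin)
    cpath <- .guard_write(
      file.path(out_dir, paste0("release_",
                                tools::file_path_sans_ext(basename(path)),
                                ".csv")), overwrite)
    write_release_curves(curve, cpath)
    files <- c(files, cpath)
    reports[[basename(path)]] <- list(
      linear_mJ_mg = int_lin$latent_heat_mJ_mg,
      sigmoidal_mJ_mg = int_sig$latent_heat_mJ_mg,
      linear_anchors_C = int_lin$anchors_C,
      sigmoidal_anchors_C = int_sig$anchors_C,
      sigmoidal_iterations = int_sig$iterations)
  }
  rpath <- .guard_write(file.path(out_dir, "integrate.json"), overwrite)
  jsonlite::write_json(reports, rpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, rpath)
  manifest <- .write_manifest(cfg, out_dir, "integrate", files)
  invisible(list(reports = reports, files = files, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_fit <- function(cfg) {
  cfg <- .as_config(cfg)
  fc <- .cfg_get(cfg, "fit", required = TRUE)
  out_dir <- cfg$out_dir
  overwrite <- isTRUE(cfg$overwrite)
  paths <- .cfg_get(fc, "curves", required = TRUE)
  curve_sets <- lapply(paths, read_release_curves)
  rates <- vapply(curve_sets, function(cs)
    attr(cs[[1]], "cooling_rate"), numeric(1))
  Tph <- .cfg_get(fc, "Tph", attr(curve_sets[[1]][[1]], "solution")$Tph)
  slow <- which.min(rates)
  fitA <- fit_temperature_constant(curve_sets[[slow]], Tph = Tph)
  fast_curves <- unlist(curve_sets[-slow], recursive = FALSE)
  fitkn <- fit_kinetics(fast_curves, A = fitA$A, Tph = Tph)
  dropped <- vapply(unlist(curve_sets, recursive = FALSE), function(cv) {
    lin <- try(avrami_linearize(cv, A = fitA$A, Tph = Tph), silent = TRUE)
    if (inherits(lin, "try-error")) NA_integer_ else lin$n_dropped
  }, integer(1))
  report <- list(
    A = fitA$A, A_r_squared = fitA$r_squared, Tph = Tph,
    k = fitkn$k, n = fitkn$n, time_unit = fitkn$time_unit,
    r_squared = as.list(fitkn$r_squared),
    dropped_points_linearization = sum(dropped, na.rm = TRUE),
    rates_used_for_A = rates[slow], rates_used_for_kn = rates[-slow])
  rpath <- .guard_write(file.path(out_dir, "fit.json"), overwrite)
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA)
  manifest <- .write_manifest(cfg, out_dir, "fit", rpath)
  invisible(list(report = report, files = rpath, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_simulate <- function(cfg) {
  cfg <- .as_config(cfg)
  sc <- .cfg_get(cfg, "simulate", required = TRUE)
  out_dir <- cfg$out_dir
  overwrite <- isTRUE(cfg$overwrite)
  sol <- .cfg_solution(sc)
  rates <- .cfg_get(sc, "cooling_rates", required = TRUE)
  N <- .cfg_get(sc, "N", 200)
  dt <- .cfg_get(sc, "dt", 1e-5)
  files <- character(0)
  diags <- list()
  for (B in rates) {
    p <- stefan_params(cooling_rate = B,
                       height = .cfg_get(sc, "height", 5e-4),
                       osmolality = sol$osmolality, slope = sol$slope)
    res <- stefan_solve(p, N = N, dt = dt,
                        gamma2_mode = .cfg_get(sc, "gamma2_mode",
                                               "temperature"))
    curve <- percent_released(res)
    df <- data.frame(t = res$trajectory$t, Z = res$trajectory$Z,
                     temperature_K = res$trajectory$temperature,
                     percent_released = res$trajectory$Z /
                       res$trajectory$Z[nrow(res$trajectory)] * 100)
    path <- .guard_write(file.path(out_dir, sprintf("simulate_B%g.csv", B)),
                         overwrite)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <- c(files, path)
    diags[[sprintf("B%g", B)]] <- res$diagnostics
  }
  dpath <- .guard_write(file.path(out_dir, "simulate_diagnostics.json"),
                        overwrite)
  jsonlite::write_json(diags, dpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, dpath)
  manifest <- .write_manifest(cfg, out_dir, "simulate", files)
  invisible(list(files = files, diagnostics = diags, manifest = manifest))
}

#' @rdname pipeline
#' @export
run_compare <- function(cfg) {
  cfg <- .as_config(cfg)
  cc <- .cfg_get(cfg, "compare", required = TRUE)
  out_dir <- cfg$out_dir
  overwrite <- isTRUE(cfg$overwrite)
  data_paths <- .cfg_get(cc, "data", required = TRUE)
  model_paths <- .cfg_get(cc, "model", required = TRUE)
  if (length(data_paths) != length(model_paths))
    stop("compare: `data` and `model` must list the same number of files",
         call. = FALSE)
  out <- list()
  for (i in seq_along(data_paths)) {
    dat <- read_release_curves(data_paths[[i]])[[1]]
    mod <- read_release_curves(model_paths[[i]])[[1]]
    pred <- stats::approx(mod$temperature, mod$fraction,
                          xout = dat$temperature, rule = 2)$y
    out[[basename(data_paths[[i]])]] <- list(
      cooling_rate = attr(dat, "cooling_rate"),
      sup_norm = max(abs(pred - dat$fraction)),
      r_squared = curve_r_squared(mod, dat))
  }
  rpath <- .guard_write(file.path(out_dir, "compare.json"), overwrite)
  jsonlite::write_json(out, rpath, auto_unbox = TRUE, digits = NA)
  manifest <- .write_manifest(cfg, out_dir, "compare", rpath)
  invisible(list(report = out, files = rpath, manifest = manifest))
}

#' Command-line dispatcher
#'
#' Thin entry point used by the installed `icecal.R` script:
#' `Rscript icecal.R <synth|integrate|fit|simulate|compare> <config.yaml>`.
#'
#' @param args Character vector: subcommand and config path.
#' @return 0 on success, 1 on error (invisibly).
#' @export
icecal_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  runners <- list(synth = run_synth, integrate = run_integrate,
                  fit = run_fit, simulate = run_simulate,
                  compare = run_compare)
  if (length(args) < 2L || !args[1] %in% names(runners)) {
    message("usage: icecal.R <", paste(names(runners), collapse = "|"),
            "> <config.yaml>")
    return(invisible(1L))
  }
  res <- try(runners[[args[1]]](args[2]), silent = TRUE)
  if (inherits(res, "try-error")) {
    message("error: ", attr(res, "condition")$message)
    return(invisible(1L))
  }
  invisible(0L)
}
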