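# Synthetic beta-galactosidase dose-response datasets.
#
# Two generators: exact model truth (for estimator recovery tests) and
# experiment-like data whose per-scenario amplitudes are calibrated to the
# published summary peaks (~200 Miller units for the operon knockout at top
# dose, ~70 for the intact luxS-null network).

#' Generator configuration for experiment-like datasets
#'
#' @param scenarios scenario labels to generate (see [scenario_label()]).
#' @param doses AI-2 dose panel (uM).
#' @param times sampling times (min); hourly on `[0, 480]` by default, as in
#'   the assay protocol.
#' @param noise_cv multiplicative log-normal noise coefficient of variation
#'   (>= 0; 0 disables noise). Default 0.10, typical bench-to-bench
#'   variability of a beta-gal assay.
#' @param seed integer seed for the noise draws.
#' @param calibration named per-scenario top-dose peak targets (Miller
#'   units). The intact (70) and operon-knockout (200) targets are the
#'   published summaries; the lsrR (120) and lsrK (10) targets are
#'   shape-preserving placeholders consistent with the qualitative
#'   descriptions (no peak is printed for those scenarios).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(scenarios = c("intact", "lsr_operon", "lsrR", "lsrK"),
                             doses = default_dose_panel(),
                             times = seq(0, 480, by = 60),
                             noise_cv = 0.10, seed = 1,
                             calibration = c(intact = 70, lsr_operon = 200,
                                             lsrR = 120, lsrK = 10)) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(calibration <= 0)) stop("calibration targets must be positive")
  for (sc in scenarios) parse_scenario(sc)
  structure(list(scenarios = scenarios, doses = sort(as.numeric(doses)),
                 times = as.numeric(times), noise_cv = noise_cv,
                 seed = as.integer(seed), calibration = calibration),
            class = "generator_config")
}

# multiplicative log-normal noise, median factor 1, CV = noise_cv
.apply_noise <- function(values, noise_cv, seed) {
  if (noise_cv == 0) return(values)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  values * exp(stats::rnorm(length(values), mean = 0, sd = sdlog))
}

#' Generate exact model-truth data
#'
#' Samples the reporter of `spec` at the given times and doses, optionally
#' corrupted by multiplicative log-normal noise. With `noise_cv = 0` the
#' dataset is exactly the model output, so [sse_objective()] at the
#' generating parameters is 0.
#'
#' @param spec a `model_spec`.
#' @param doses doses (uM).
#' @param times sampling times (min).
#' @param seed integer seed (used only when `noise_cv > 0`).
#' @param noise_cv multiplicative noise CV.
#' @param rtol,atol integration tolerances.
#' @return An `lsr_dataset` with attribute `generator` recording the inputs.
#' @export
generate_model_truth <- function(spec, doses = default_dose_panel(),
                                 times = seq(0, 480, by = 60), seed = 1,
                                 noise_cv = 0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"))
  grid <- if (times[1] > 0) c(0, times) else times
  recs <- lapply(sort(as.numeric(doses)), function(d) {
    traj <- integrate_timecourse(spec, d, grid, rtol = rtol, atol = atol)
    data.frame(scenario = scenario_label(spec$knockouts), dose_uM = d,
               time_min = times,
               miller_units = traj$reporter[match(times, traj$times)])
  })
  df <- do.call(rbind, recs)
  df$miller_units <- .apply_noise(df$miller_units, noise_cv, seed)
  out <- experimental_dataset(df)
  attr(out, "generator") <- list(kind = "model_truth", variant = spec$variant,
                                 scenario = scenario_label(spec$knockouts),
                                 params = unclass(spec$params),
                                 noise_cv = noise_cv, seed = seed)
  out
}

#' Generate an experiment-like calibrated dataset
#'
#' Emulates the wet-lab assay: for each scenario the full (REG-binding)
#' model is run with the published best-fit parameters, and the reporter is
#' rescaled by one per-scenario factor so that the noise-free top-dose peak
#' equals the scenario's calibration target exactly. Model dynamics (shape,
#' dose ordering, peak times) are preserved; only the unknowable absolute
#' Miller-unit scale is set. Noise is applied after calibration.
#'
#' @param config a [generator_config()].
#' @param params generating parameters (published best-fit values by
#'   default).
#' @param variant generating topology (the full REG-binding model).
#' @param rtol,atol integration tolerances.
#' @return An `lsr_dataset`; attribute `generator` records config, seed,
#'   per-scenario scale factors and the generating parameters, so fits can
#'   invert the calibration.
#' @examples
#' cfg <- generator_config(noise_cv = 0)
#' ds <- generate_experiment_like(cfg)
#' max(ds$miller_units[ds$scenario == "lsr_operon"])  # 200
#' @export
generate_experiment_like <- function(config = generator_config(),
                                     params = kinetic_params(),
                                     variant = "reg_binding",
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "generator_config"))
  params <- as_kinetic_params(params)
  miss <- setdiff(config$scenarios, names(config$calibration))
  if (length(miss))
    stop("missing calibration target(s) for scenario(s): ",
         paste(miss, collapse = ", "))
  top <- max(config$doses)
  grid <- if (config$times[1] > 0) c(0, config$times) else config$times

  scales <- stats::setNames(numeric(length(config$scenarios)), config$scenarios)
  parts <- vector("list", length(config$scenarios))
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[i]
    spec <- model_spec(variant, parse_scenario(sc), params)
    trajs <- lapply(config$doses, function(d)
      integrate_timecourse(spec, d, grid, rtol = rtol, atol = atol))
    raw <- vapply(trajs, function(tr)
      tr$reporter[match(config$times, tr$times)],
      numeric(length(config$times)))
    raw_peak <- max(raw[, which(config$doses == top)])
    if (raw_peak <= 0)
      stop("scenario '", sc, "': top-dose reporter peak is zero, cannot calibrate")
    scales[sc] <- config$calibration[[sc]] / raw_peak
    parts[[i]] <- data.frame(
      scenario = sc,
      dose_uM = rep(config$doses, each = length(config$times)),
      time_min = rep(config$times, times = length(config$doses)),
      miller_units = as.vector(raw) * scales[sc])
  }
  df <- do.call(rbind, parts)
  df$miller_units <- .apply_noise(df$miller_units, config$noise_cv, config$seed)
  out <- experimental_dataset(df)
  attr(out, "generator") <- list(kind = "experiment_like", variant = variant,
                                 config = unclass(config),
                                 scales = as.list(scales),
                                 params = unclass(params))
  out
}

#' Write a synthetic dataset with its JSON sidecar
#'
#' Writes the CSV (see [write_timecourse_csv()]) plus `<path>.json` holding
#' the generator provenance (kind, config, seed, per-scenario scales,
#' generating parameters).
#'
#' @param data an `lsr_dataset` produced by a generator in this package.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(data, path) {
  write_timecourse_csv(data, path)
  gen <- attr(data, "generator")
  if (!is.null(gen))
    jsonlite::write_json(gen, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = I(17))
  invisible(path)
}
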