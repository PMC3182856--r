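# Least-squares parameter estimation by Hooke-Jeeves direct search with
# Latin-hypercube multistart. Positive rate/affinity parameters are searched
# in log coordinates; Hill coefficients are searched linearly.

.LOG_SCALE <- c("k_op", "k_r", "k1", "k2", "k3", "k4", "k5",
                "k_f", "k_imp", "k_deg", "s_rep")

#' Default fitting bounds
#'
#' Rates and binding constants span `[1e-4, 1e2]` (natural units), repression
#' coefficients `[1e-2, 1e2]` uM, Hill coefficients `[1, 6]`, protein decay
#' `[1e-4, 1]` 1/min and the reporter scale `[1e-3, 1e3]`. These bracket every
#' published best-fit value by at least two decades.
#'
#' @return Named list of `c(lower, upper)` per parameter.
#' @export
default_bounds <- function() {
  b <- list()
  for (nm in c("k_op", "k_r", "k3", "k5", "k_f", "k_imp")) b[[nm]] <- c(1e-4, 1e2)
  for (nm in c("k1", "k2", "k4")) b[[nm]] <- c(1e-2, 1e2)
  for (nm in c("nOP", "nR", "nG")) b[[nm]] <- c(1, 6)
  b$k_deg <- c(1e-4, 1)
  b$s_rep <- c(1e-3, 1e3)
  b
}

#' Fit configuration
#'
#' @param free character vector of free parameter names (a subset of the
#'   [kinetic_params()] fields). `k_deg` is fixed by default: protein decay is
#'   set by the cell division time, not estimated.
#' @param params base `kinetic_params`: values for all fixed parameters and
#'   the default start for free ones.
#' @param bounds named list of `c(lower, upper)`; see [default_bounds()].
#' @param start optional named numeric start values for the free parameters
#'   (defaults to their values in `params`).
#' @param restarts number of additional Latin-hypercube starts (the `start`
#'   point is always run first).
#' @param seed integer seed for the Latin-hypercube draws.
#' @param step_init initial Hooke-Jeeves step as a fraction of each (possibly
#'   log-transformed) bound range.
#' @param step_reduce step reduction factor on a failed exploratory sweep.
#' @param tol relative step-size convergence threshold (relative to the
#'   initial step).
#' @param max_evals objective evaluation budget per restart.
#' @param rtol,atol integration tolerances used inside the objective.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = c("k_op", "k_r", "k1", "k2", "k3", "nOP", "nR"),
                       params = kinetic_params(), bounds = default_bounds(),
                       start = NULL, restarts = 20, seed = 1,
                       step_init = 0.25, step_reduce = 0.5, tol = 1e-4,
                       max_evals = 1e4, rtol = 1e-8, atol = 1e-10) {
  params <- as_kinetic_params(params)
  bad <- setdiff(free, .PARAM_NAMES)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if ("k_deg" %in% free)
    warning("k_deg is conventionally fixed at the cell-division dilution rate")
  for (nm in free) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2] ||
        (nm %in% .LOG_SCALE && b[1] <= 0))
      stop("invalid bounds for '", nm, "'")
  }
  if (!is.null(start)) {
    if (!all(free %in% names(start)))
      stop("start must name every free parameter")
    start <- start[free]
  }
  structure(list(free = free, params = params, bounds = bounds[free],
                 start = start, restarts = as.integer(restarts),
                 seed = as.integer(seed), step_init = step_init,
                 step_reduce = step_reduce, tol = tol,
                 max_evals = as.integer(max_evals), rtol = rtol, atol = atol),
            class = "fit_config")
}

#' Weighted sum-of-squares objective
#'
#' For every (scenario, dose) pair in the dataset the model is integrated
#' once, the reporter is read off at the record times, and the weighted
#' squared residuals are summed. Integration failures do not abort the
#' search: the objective returns a large penalty (`1e12`) flagged with
#' attribute `failed = TRUE`.
#'
#' @param p a `kinetic_params` (inadmissible sets are penalized, not errors).
#' @param data an `lsr_dataset` (see [experimental_dataset()]).
#' @param variant model topology, see [model_variant()].
#' @param rtol,atol integration tolerances.
#' @return SSE (Miller units squared).
#' @export
sse_objective <- function(p, data, variant = "reg_binding",
                          rtol = 1e-8, atol = 1e-10) {
  p <- as_kinetic_params(p)
  # validated datasets pass through; optimizers call this in a tight loop
  if (!inherits(data, "lsr_dataset"))
    data <- experimental_dataset(as.data.frame(data))
  if (length(validate_params(p)))
    return(structure(1e12, failed = TRUE))
  sse <- 0
  for (sc in unique(data$scenario)) {
    spec <- model_spec(variant, parse_scenario(sc), p)
    dsub <- data[data$scenario == sc, ]
    for (d in unique(dsub$dose_uM)) {
      rec <- dsub[dsub$dose_uM == d, ]
      tt <- sort(unique(rec$time_min))
      grid <- if (tt[1] > 0) c(0, tt) else tt
      traj <- tryCatch(
        integrate_timecourse(spec, d, grid, rtol = rtol, atol = atol),
        error = function(e) NULL)
      if (is.null(traj)) return(structure(1e12, failed = TRUE))
      pred <- traj$reporter[match(rec$time_min, traj$times)]
      sse <- sse + sum(rec$weight * (pred - rec$miller_units)^2)
    }
  }
  sse
}

#' Hooke-Jeeves direct search
#'
#' Classic pattern search: an exploratory sweep over coordinate steps around
#' the current base, followed by pattern (extrapolation) moves while they
#' keep paying off; coordinate steps shrink by `step_reduce` when a sweep
#' fails. Terminates when every step has fallen below `tol` times its initial
#' value or the evaluation budget is spent. All iterates are projected onto
#' the box `[lower, upper]`. Deterministic for fixed inputs.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param start numeric start point, within bounds.
#' @param lower,upper bounds (recycled to the dimension of `start`).
#' @param step_init initial step per coordinate (recycled); default 25% of
#'   the bound range.
#' @param step_reduce multiplicative step reduction on failure.
#' @param tol relative step-size termination threshold.
#' @param max_evals objective evaluation budget.
#' @return List with `par`, `value`, `evals`, `converged`, and `trace`
#'   (data.frame of best-so-far values).
#' @export
hooke_jeeves_minimize <- function(objective, start, lower, upper,
                                  step_init = NULL, step_reduce = 0.5,
                                  tol = 1e-4, max_evals = 1e4) {
  d <- length(start)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(start < lower | start > upper))
    stop("start point outside bounds")
  if (is.null(step_init)) step_init <- 0.25 * (upper - lower)
  step_init <- rep_len(step_init, d)
  step <- step_init

  clamp <- function(x) pmin(pmax(x, lower), upper)
  evals <- 0L
  fwrap <- function(x) { evals <<- evals + 1L; as.numeric(objective(x)) }

  base <- start
  fbase <- fwrap(base)
  trace_evals <- evals; trace_f <- fbase

  explore <- function(x, fx) {
    for (i in seq_len(d)) {
      for (s in c(step[i], -step[i])) {
        if (evals >= max_evals) break
        xi <- x; xi[i] <- min(max(xi[i] + s, lower[i]), upper[i])
        if (xi[i] == x[i]) next
        fi <- fwrap(xi)
        if (fi < fx) { x <- xi; fx <- fi; break }
      }
    }
    list(x = x, f = fx)
  }

  converged <- FALSE
  while (evals < max_evals) {
    ex <- explore(base, fbase)
    if (ex$f < fbase) {
      # pattern moves while they improve
      prev <- base
      base <- ex$x; fbase <- ex$f
      while (evals < max_evals) {
        pat <- clamp(base + (base - prev))
        ex2 <- explore(pat, fwrap(pat))
        if (ex2$f < fbase) { prev <- base; base <- ex2$x; fbase <- ex2$f }
        else break
      }
    } else {
      step <- step * step_reduce
      if (all(step < tol * step_init)) { converged <- TRUE; break }
    }
    trace_evals <- c(trace_evals, evals); trace_f <- c(trace_f, fbase)
  }
  list(par = base, value = fbase, evals = evals, converged = converged,
       trace = data.frame(evals = trace_evals, best = trace_f))
}

#' Latin-hypercube start points
#'
#' Stratified per dimension: one point per stratum in a random permutation,
#' uniform within each stratum. Dimensions flagged log-scale are stratified
#' log-uniformly. Reproducible under `seed`; the global RNG state is
#' restored afterwards.
#'
#' @param bounds named list of `c(lower, upper)` per dimension.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @param log_scale logical per dimension (default: by parameter name,
#'   `TRUE` for everything except Hill coefficients).
#' @return `n` x `d` matrix, columns named as `bounds`, values in natural
#'   units.
#' @export
latin_hypercube_starts <- function(bounds, n, seed = 1, log_scale = NULL) {
  stopifnot(n >= 1)
  d <- length(bounds)
  if (is.null(log_scale)) log_scale <- names(bounds) %in% .LOG_SCALE
  log_scale <- rep_len(log_scale, d)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- matrix(NA_real_, n, d, dimnames = list(NULL, names(bounds)))
  for (j in seq_len(d)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    if (log_scale[j]) { lo <- log(lo); hi <- log(hi) }
    u <- (sample.int(n) - stats::runif(n)) / n  # one draw per stratum
    x <- lo + u * (hi - lo)
    out[, j] <- if (log_scale[j]) exp(x) else x
  }
  out
}

# transform free parameters to search coordinates and back
.to_coord <- function(x, names) ifelse(names %in% .LOG_SCALE, log(x), x)
.from_coord <- function(z, names) ifelse(names %in% .LOG_SCALE, exp(z), z)

#' Fit a model variant to a dataset
#'
#' Minimizes [sse_objective()] over the free parameters of `config` by
#' [hooke_jeeves_minimize()], searching log coordinates for positive
#' rate/affinity parameters and linear coordinates for Hill exponents. The
#' configured start (the base parameter values by default) is always run
#' first; `config$restarts` additional Latin-hypercube starts follow.
#'
#' @param data an `lsr_dataset`; scenarios are taken from its records.
#' @param variant model topology, see [model_variant()].
#' @param config a [fit_config()].
#' @return An object of class `lsr_fit`: best `params` (full
#'   `kinetic_params`), `sse`, `restarts` summary data.frame, `traces`,
#'   `seed`, `free`, `bounds`, `variant`, `converged`.
#' @examples
#' \donttest{
#' truth <- model_spec("reg_binding")
#' data <- generate_model_truth(truth, doses = c(5, 40),
#'                              times = seq(0, 480, by = 60))
#' cfg <- fit_config(free = "k1", start = c(k1 = 0.6), restarts = 0)
#' fit <- fit_model(data, "reg_binding", cfg)
#' fit$params$k1  # ~0.2
#' }
#' @export
fit_model <- function(data, variant = "reg_binding", config = fit_config()) {
  data <- experimental_dataset(as.data.frame(data))
  stopifnot(inherits(config, "fit_config"))
  variant <- model_variant(variant)
  free <- config$free
  d <- length(free)

  lower <- .to_coord(vapply(config$bounds, `[`, 0.0, 1L), free)
  upper <- .to_coord(vapply(config$bounds, `[`, 0.0, 2L), free)
  step_init <- config$step_init * (upper - lower)

  make_params <- function(z) {
    p <- unclass(config$params)
    p[free] <- as.list(.from_coord(z, free))
    structure(p, class = "kinetic_params")
  }
  obj <- function(z) sse_objective(make_params(z), data, variant,
                                   rtol = config$rtol, atol = config$atol)

  start0 <- config$start
  if (is.null(start0))
    start0 <- vapply(free, function(nm) config$params[[nm]], 0.0)
  z0 <- pmin(pmax(.to_coord(start0, free), lower), upper)
  starts <- list(z0)
  if (config$restarts > 0) {
    lhs <- latin_hypercube_starts(config$bounds, config$restarts, config$seed)
    for (i in seq_len(nrow(lhs))) starts[[i + 1L]] <- .to_coord(lhs[i, ], free)
  }

  runs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    runs[[i]] <- tryCatch(
      hooke_jeeves_minimize(obj, starts[[i]], lower, upper,
                            step_init = step_init,
                            step_reduce = config$step_reduce,
                            tol = config$tol, max_evals = config$max_evals),
      error = function(e) list(error = conditionMessage(e)))
  }
  ok <- !vapply(runs, function(r) !is.null(r$error), TRUE)
  if (!any(ok))
    stop("all restarts failed: ",
         paste(unique(vapply(runs, `[[`, "", "error")), collapse = "; "))
  values <- vapply(runs, function(r) if (is.null(r$error)) r$value else Inf, 0.0)
  best <- which.min(values)

  restart_summary <- data.frame(
    restart = seq_along(runs) - 1L,
    sse = values,
    evals = vapply(runs, function(r) if (is.null(r$error)) r$evals else NA_integer_, 0L),
    converged = vapply(runs, function(r) isTRUE(r$converged), TRUE))

  structure(
    list(params = make_params(runs[[best]]$par), sse = values[best],
         variant = variant, free = free, bounds = config$bounds,
         seed = config$seed, restarts = restart_summary,
         traces = lapply(runs, function(r) r$trace),
         converged = isTRUE(runs[[best]]$converged),
         best_restart = best - 1L),
    class = "lsr_fit")
}

#' @export
print.lsr_fit <- function(x, ...) {
  cat(sprintf("<lsr_fit> %s, SSE = %.6g (%d restart(s), best #%d%s)\n",
              x$variant, x$sse, nrow(x$restarts), x$best_restart,
              if (x$converged) ", converged" else ""))
  for (nm in x$free) cat(sprintf("  %-6s %g\n", nm, x$params[[nm]]))
  invisible(x)
}

#' Write / read a fit result as JSON
#'
#' Serializes the full provenance of a fit (parameters, SSE, free-parameter
#' mask, bounds, seed, restart summary) at full numeric precision so the
#' round trip is lossless.
#'
#' @param fit an `lsr_fit`.
#' @param path JSON file path.
#' @return `write_fit_result()` returns `path` invisibly;
#'   `read_fit_result()` returns the `lsr_fit` (without the per-restart
#'   traces, which are summarized, not archived).
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "lsr_fit"))
  payload <- list(
    package_version = as.character(utils::packageVersion("lsrswitch")),
    variant = fit$variant, free = as.list(fit$free),
    params = unclass(fit$params), sse = fit$sse, seed = fit$seed,
    bounds = fit$bounds, restarts = fit$restarts,
    converged = fit$converged, best_restart = fit$best_restart)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) {
  if (!file.exists(path)) stop("fit result not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(params = as_kinetic_params(as.list(x$params)), sse = x$sse,
         variant = x$variant, free = unlist(x$free),
         bounds = lapply(x$bounds, as.numeric), seed = x$seed,
         restarts = as.data.frame(x$restarts), traces = NULL,
         converged = x$converged, best_restart = x$best_restart),
    class = "lsr_fit")
}
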