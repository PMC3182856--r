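# Kinetic parameters of the lsr AI-2 uptake models.

# canonical ordering shared with the compiled right-hand side
.PARAM_NAMES <- c("k_op", "k_r", "k1", "k2", "k3", "k4", "k5",
                  "k_f", "k_imp", "nOP", "nR", "nG", "k_deg", "s_rep")
.HILL_NAMES <- c("nOP", "nR", "nG")

#' Kinetic parameter set for the lsr circuit models
#'
#' Constructs the full set of rate, affinity and cooperativity constants used
#' by all model variants. Defaults are the published best-fit values of the
#' modified (REG-binding) model, with two reconstruction additions: `nG`, the
#' Hill cooperativity of REG repression (default 1, no evidence of
#' cooperativity), and `s_rep`, the reporter calibration scalar converting
#' reporter protein concentration (uM) to Miller units (default 1).
#'
#' @param k_op maximal lsr-promoter synthesis rate for the Lsr transporter,
#'   the REG regulator and the reporter (uM/min).
#' @param k_r maximal LsrR synthesis rate (uM/min).
#' @param k1 LsrR -> lsr-operon repression coefficient (uM).
#' @param k2 LsrR auto-repression coefficient (uM).
#' @param k3 AI-2-P/LsrR binding rate (1/uM/min).
#' @param k4 REG -> lsr-operon repression coefficient (uM).
#' @param k5 AI-2-P/REG binding rate (1/uM/min).
#' @param k_f alternative-pathway AI-2 import rate, first order in external
#'   AI-2 (1/min).
#' @param k_imp Lsr-transporter AI-2 import rate (1/uM/min).
#' @param nOP Hill cooperativity of operon repression (>= 1).
#' @param nR Hill cooperativity of LsrR auto-repression (>= 1).
#' @param nG Hill cooperativity of REG repression (>= 1).
#' @param k_deg protein decay/dilution rate (1/min).
#' @param s_rep Miller units per uM of reporter protein.
#' @return An object of class `kinetic_params` (named numeric list).
#' @examples
#' p <- kinetic_params()           # published best-fit values
#' p2 <- kinetic_params(k1 = 0.5)  # override one constant
#' @export
kinetic_params <- function(k_op = 7, k_r = 2, k1 = 0.2, k2 = 0.1, k3 = 0.05,
                           k4 = 65, k5 = 1e-4, k_f = 0.01, k_imp = 0.01,
                           nOP = 4, nR = 4, nG = 1, k_deg = 0.02, s_rep = 1) {
  p <- list(k_op = k_op, k_r = k_r, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
            k5 = k5, k_f = k_f, k_imp = k_imp, nOP = nOP, nR = nR, nG = nG,
            k_deg = k_deg, s_rep = s_rep)
  for (nm in .PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "kinetic_params")
}

#' Validate a kinetic parameter set
#'
#' Checks every invariant of [kinetic_params()]: all constants non-negative
#' and every Hill coefficient at least 1. Returns the violations instead of
#' erroring so that optimizers and I/O code can report them all at once.
#'
#' @param p a `kinetic_params` object or a named list coercible to one.
#' @return Character vector of violation messages, each naming the offending
#'   field; `character(0)` if the set is admissible.
#' @examples
#' validate_params(kinetic_params())           # character(0)
#' validate_params(kinetic_params(k1 = -0.1))  # names k1
#' @export
validate_params <- function(p) {
  p <- as_kinetic_params(p)
  bad <- character(0)
  for (nm in .PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.finite(v))
      bad <- c(bad, sprintf("%s: must be finite (got %g)", nm, v))
    else if (v < 0)
      bad <- c(bad, sprintf("%s: must be >= 0 (got %g)", nm, v))
  }
  for (nm in .HILL_NAMES) {
    v <- p[[nm]]
    if (is.finite(v) && v < 1)
      bad <- c(bad, sprintf("%s: Hill coefficient must be >= 1 (got %g)", nm, v))
  }
  bad
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  for (nm in .PARAM_NAMES) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Coerce a named list / named numeric vector to kinetic_params, filling
# unspecified fields with the defaults.
#' @rdname kinetic_params
#' @param x a `kinetic_params`, named list or named numeric vector.
#' @export
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) x <- as.list(x)
  if (!is.list(x)) stop("cannot coerce to kinetic_params: need a named list")
  unknown <- setdiff(names(x), .PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  do.call(kinetic_params, x)
}

# numeric vector in canonical order (without s_rep) for the compiled code
.param_vector <- function(p) {
  vapply(.PARAM_NAMES[.PARAM_NAMES != "s_rep"], function(nm) p[[nm]], 0.0)
}

#' Read / write kinetic parameter sets as JSON
#'
#' Parameter files are flat JSON objects keyed by the field names of
#' [kinetic_params()]; missing keys take their default value.
#'
#' @param path file path.
#' @return `read_params_json()` returns a `kinetic_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  as_kinetic_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_params_json
#' @param p a `kinetic_params` object.
#' @export
write_params_json <- function(p, path) {
  p <- as_kinetic_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
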