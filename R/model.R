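# Model topologies, knockout transforms and the ODE right-hand side.
#
# All modelled scenarios are luxS-null: the cell synthesizes no AI-2 and the
# only source is the external dose Aout(0). The state vector is
#   OP    Lsr transporter (uM)
#   G     REG regulator (uM; identically 0 in the FIRST variant)
#   R     LsrR repressor (uM)
#   Ap    phospho-AI-2 (uM)
#   U     unphosphorylated internal AI-2 (uM; only grows under lsrK knockout)
#   Aout  external AI-2 (uM)
#   C_R   LsrR:AI-2-P complex (uM)
#   C_G   REG:AI-2-P complex (uM)
#   Y     reporter protein (uM); Miller units = s_rep * Y

.STATE_NAMES <- c("OP", "G", "R", "Ap", "U", "Aout", "C_R", "C_G", "Y")
.VARIANTS <- c("first", "reg_no_binding", "reg_binding")
.KNOCKOUT_NAMES <- c("lsr_operon", "lsrR", "lsrK")

#' Model variants of the lsr circuit
#'
#' Three nested topologies are supported:
#' * `"first"` — LsrR is the only lsr-promoter repressor.
#' * `"reg_no_binding"` — a second lsr-encoded repressor REG is added
#'   (repression coefficient `k4`) but REG does not bind AI-2-P (`k5` forced
#'   to 0).
#' * `"reg_binding"` — the full modified model: REG represses the promoter
#'   and is itself sequestered by AI-2-P (`k5` active).
#'
#' @param variant character, matched against the three names above.
#' @return The canonical variant string.
#' @export
model_variant <- function(variant = c("first", "reg_no_binding", "reg_binding")) {
  match.arg(variant)
}

#' Knockout set
#'
#' Any subset of `{"lsr_operon", "lsrR", "lsrK"}`; the empty set is the
#' intact (luxS-only knockout) network.
#'
#' @param knockouts character vector of gene names to delete.
#' @return Named logical vector with elements `lsr_operon`, `lsrR`, `lsrK`.
#' @export
knockout_set <- function(knockouts = character(0)) {
  if (is.logical(knockouts) && !is.null(names(knockouts)))
    knockouts <- names(knockouts)[knockouts]
  knockouts <- as.character(knockouts)
  bad <- setdiff(knockouts, .KNOCKOUT_NAMES)
  if (length(bad))
    stop("unknown knockout(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(.KNOCKOUT_NAMES, collapse = ", "), ")")
  stats::setNames(.KNOCKOUT_NAMES %in% knockouts, .KNOCKOUT_NAMES)
}

#' Scenario labels
#'
#' A scenario is the canonical string form of a knockout set: knockouts
#' joined by `"+"` in fixed order, or `"intact"` for the empty set.
#'
#' @param knockouts a knockout set (see [knockout_set()]).
#' @return Scenario label string.
#' @export
scenario_label <- function(knockouts) {
  ko <- knockout_set(knockouts)
  if (!any(ko)) "intact" else paste(names(ko)[ko], collapse = "+")
}

#' @rdname scenario_label
#' @param label a scenario label.
#' @export
parse_scenario <- function(label) {
  if (identical(label, "intact")) return(knockout_set())
  knockout_set(strsplit(label, "+", fixed = TRUE)[[1L]])
}

#' Model specification
#'
#' Binds a topology variant, a knockout set and a kinetic parameter set into
#' the unit that the integrator and the fitting machinery consume.
#'
#' @param variant see [model_variant()].
#' @param knockouts see [knockout_set()]; also accepts a scenario label.
#' @param params see [kinetic_params()].
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("reg_binding", "lsr_operon", kinetic_params())
#' @export
model_spec <- function(variant = "reg_binding", knockouts = character(0),
                       params = kinetic_params()) {
  if (is.character(knockouts) && length(knockouts) == 1L &&
      (identical(knockouts, "intact") || grepl("+", knockouts, fixed = TRUE)))
    knockouts <- parse_scenario(knockouts)
  spec <- structure(
    list(variant = model_variant(variant),
         knockouts = knockout_set(knockouts),
         params = as_kinetic_params(params)),
    class = "model_spec")
  viol <- validate_params(spec$params)
  if (length(viol))
    stop("inadmissible parameters: ", paste(viol, collapse = "; "))
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> variant:", x$variant,
      " scenario:", scenario_label(x$knockouts), "\n")
  invisible(x)
}

# Hill repression factor 1/(1 + (x/K)^n); x = 0 gives exactly 1.
.hill_repress <- function(x, K, n) {
  if (x == 0) return(1)
  if (K <= 0) stop("repression coefficient must be > 0 when repressor is present")
  1 / (1 + (x / K)^n)
}

#' lsr-promoter activity
#'
#' The synthesis rate driven by the lsr promoter: maximal rate `k_op`
#' attenuated by Hill repression from free LsrR and — in the REG variants —
#' multiplicatively by Hill repression from free REG.
#'
#' @param R free LsrR concentration (uM).
#' @param G free REG concentration (uM); ignored by the `"first"` variant.
#' @param p a `kinetic_params`.
#' @param variant see [model_variant()].
#' @return Synthesis rate (uM/min), in `(0, k_op]`.
#' @examples
#' promoter_activity(0, 0, kinetic_params())   # = k_op
#' @export
promoter_activity <- function(R, G = 0, p = kinetic_params(),
                              variant = "reg_binding") {
  variant <- model_variant(variant)
  p <- as_kinetic_params(p)
  if (R < 0 || G < 0) stop("repressor concentrations must be >= 0")
  act <- p$k_op * .hill_repress(R, p$k1, p$nOP)
  if (variant != "first") act <- act * .hill_repress(G, p$k4, p$nG)
  act
}

# effective AI-2-P/REG binding rate for a variant
.k5_effective <- function(p, variant) {
  if (identical(variant, "reg_binding")) p$k5 else 0
}

#' ODE right-hand side
#'
#' Evaluates the time derivative of the full state for a model specification,
#' with knockout transforms applied (see [apply_knockouts()]). This is the
#' reference R implementation; the integrator uses an equivalent compiled
#' version.
#'
#' @param state named numeric vector over the nine state variables (see
#'   [state_template()]).
#' @param p a `kinetic_params` (defaults to `spec$params`).
#' @param spec a `model_spec`.
#' @return Named numeric derivative vector (uM/min).
#' @export
lsr_rhs <- function(state, p = spec$params, spec) {
  if (any(!is.finite(state))) stop("non-finite state passed to lsr_rhs")
  state <- state[.STATE_NAMES]
  if (any(is.na(state))) stop("state must be named over ", paste(.STATE_NAMES, collapse = ", "))
  p <- as_kinetic_params(p)
  ko <- spec$knockouts
  variant <- spec$variant
  has_reg <- variant != "first"
  k5e <- .k5_effective(p, variant)

  OP <- state[["OP"]]; G <- state[["G"]]; R <- state[["R"]]
  Ap <- state[["Ap"]]; Aout <- state[["Aout"]]
  C_R <- state[["C_R"]]; C_G <- state[["C_G"]]; Y <- state[["Y"]]

  if (ko[["lsrR"]]) R <- 0
  if (ko[["lsrK"]]) Ap <- 0
  if (!has_reg) G <- 0

  P <- promoter_activity(R, G, p, variant)
  import <- (p$k_imp * OP + p$k_f) * Aout

  d <- stats::setNames(numeric(length(.STATE_NAMES)), .STATE_NAMES)
  d[["OP"]] <- (if (ko[["lsr_operon"]]) 0 else P) - p$k_deg * OP
  if (has_reg)
    d[["G"]] <- (if (ko[["lsr_operon"]]) 0 else P) - p$k_deg * G - k5e * G * Ap
  if (!ko[["lsrR"]])
    d[["R"]] <- p$k_r * .hill_repress(R, p$k2, p$nR) - p$k_deg * R - p$k3 * R * Ap
  if (ko[["lsrK"]]) {
    d[["U"]] <- import
  } else {
    d[["Ap"]] <- import - p$k3 * R * Ap - k5e * G * Ap
  }
  d[["Aout"]] <- -import
  d[["C_R"]] <- p$k3 * R * Ap - p$k_deg * C_R
  if (has_reg) d[["C_G"]] <- k5e * G * Ap - p$k_deg * C_G
  d[["Y"]] <- P - p$k_deg * Y
  d
}

#' Initial state template
#'
#' All species start at zero except external AI-2, which is set to the dose.
#'
#' @param dose external AI-2 concentration (uM), in `[0, 40]` for the
#'   modelled experiments (larger values are permitted but extrapolate).
#' @return Named numeric vector over the nine state variables.
#' @export
state_template <- function(dose = 0) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("dose must be a single non-negative number")
  s <- stats::setNames(numeric(length(.STATE_NAMES)), .STATE_NAMES)
  s[["Aout"]] <- dose
  s
}

#' Compile a model specification into a derivative function
#'
#' Applies the knockout transforms and returns `function(t, state)` suitable
#' for any explicit integrator. Knockout semantics:
#' * `lsr_operon` — OP and REG synthesis are removed (both are driven by the
#'   deleted operon's promoter); AI-2 import reduces to the alternative
#'   pathway `k_f * Aout`. The reporter fusion remains and still reads out
#'   promoter activity.
#' * `lsrR` — LsrR is absent: `R` is pinned at 0 and its equation removed.
#' * `lsrK` — no phosphorylation: imported AI-2 accumulates in the inert
#'   pool `U` and `Ap` stays 0, locking the promoter in its repressed state.
#'
#' @param spec a `model_spec`.
#' @return Function `(t, state) -> derivative`, closing over the spec.
#' @export
apply_knockouts <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  force(spec)
  function(t, state) lsr_rhs(state, spec$params, spec)
}

# integer flags for the compiled right-hand side
.spec_flags <- function(spec) {
  c(variant = match(spec$variant, .VARIANTS) - 1L,
    ko_op = as.integer(spec$knockouts[["lsr_operon"]]),
    ko_R = as.integer(spec$knockouts[["lsrR"]]),
    ko_K = as.integer(spec$knockouts[["lsrK"]]))
}
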