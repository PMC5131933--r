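#' Ionic-remodeling scenario
#'
#' A named set of multipliers on maximal conductances / fluxes of the
#' Courtemanche atrial cell model plus a diffusion scale. The control
#' scenario is all multipliers at 1. Multiplier names:
#' `g_Na` (fast sodium), `g_to` (transient outward), `g_CaL` (L-type
#' calcium), `g_Kur` (ultrarapid delayed rectifier), `g_K1` (inward
#' rectifier), `k_NaCa_max` (Na/Ca exchanger maximum), `sr_leak`
#' (sarcoplasmic-reticulum calcium leak), `D_scale` (gap-junctional
#' coupling, applied to the diffusion coefficient).
#'
#' @param ... Named multipliers overriding the control value of 1, e.g.
#'   `g_CaL = 0.3`. All must be positive; unknown names are rejected.
#' @param name Scenario label stored in movie provenance.
#' @return An object of class `scenario_config` (named numeric vector of the
#'   eight multipliers plus a `name` attribute).
#' @seealso [scenario_preset()] for the standard study conditions.
#' @export
scenario_config <- function(..., name = NULL) {
  mult <- c(g_Na = 1, g_to = 1, g_CaL = 1, g_Kur = 1, g_K1 = 1,
            k_NaCa_max = 1, sr_leak = 1, D_scale = 1)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("scenario multipliers must be named")
    bad <- setdiff(names(ov), names(mult))
    if (length(bad))
      stop("unknown scenario multiplier(s): ", paste(bad, collapse = ", "))
    ovn <- unlist(ov)
    if (any(!is.finite(ovn)) || any(ovn <= 0))
      stop("scenario multipliers must be positive")
    mult[names(ov)] <- ovn
  }
  if (is.null(name))
    name <- if (all(mult == 1)) "control" else "custom"
  structure(list(multipliers = mult, name = name), class = "scenario_config")
}

#' Standard remodeling scenarios
#'
#' Presets for the study conditions:
#' \describe{
#'   \item{`control`}{all multipliers 1.}
#'   \item{`0.3xICaL`}{L-type calcium conductance reduced by 70%; yields a
#'     stable rotor.}
#'   \item{`0.7xINa`}{sodium conductance reduced by 30%.}
#'   \item{`AF`}{the seven-multiplier atrial-fibrillation remodeling set:
#'     I_Na -10%, I_to -70%, I_CaL -70%, I_Kur -50%, SR Ca leak +25%,
#'     I_K1 +100%, I_NaCa(max) +40%.}
#'   \item{`0.7xD`}{gap-junctional coupling reduced by 30%.}
#'   \item{`0.3xD`}{gap-junctional coupling reduced by 70%.}
#' }
#'
#' @param name One of `"control"`, `"0.3xICaL"`, `"0.7xINa"`, `"AF"`,
#'   `"0.7xD"`, `"0.3xD"`.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("control", "0.3xICaL", "0.7xINa", "AF",
                                     "0.7xD", "0.3xD")) {
  name <- match.arg(name)
  switch(name,
    "control"  = scenario_config(name = "control"),
    "0.3xICaL" = scenario_config(g_CaL = 0.3, name = "0.3xICaL"),
    "0.7xINa"  = scenario_config(g_Na = 0.7, name = "0.7xINa"),
    "AF"       = scenario_config(g_Na = 0.9, g_to = 0.3, g_CaL = 0.3,
                                 g_Kur = 0.5, sr_leak = 1.25, g_K1 = 2.0,
                                 k_NaCa_max = 1.4, name = "AF"),
    "0.7xD"    = scenario_config(D_scale = 0.7, name = "0.7xD"),
    "0.3xD"    = scenario_config(D_scale = 0.3, name = "0.3xD"))
}

#' Baseline Courtemanche cell-model parameters
#'
#' The maximal conductances and fluxes of the Courtemanche-Ramirez-Nattel
#' human atrial model that remodeling scenarios act on, in pA/pF-compatible
#' units, plus the tissue diffusion coefficient slot `D_cm2_per_ms`.
#'
#' @param D_cm2_per_ms Diffusion coefficient carried alongside the cell
#'   parameters so that `D_scale` scenarios can act on it.
#' @return Named numeric vector of baseline parameters.
#' @export
courtemanche_params <- function(D_cm2_per_ms = 0.001) {
  c(g_Na = 7.8, g_to = 0.1652, g_CaL = 0.12375, g_Kur = 1.0, g_K1 = 0.09,
    k_NaCa_max = 1600, sr_leak = 1.0, D_cm2_per_ms = D_cm2_per_ms)
}

#' Apply a remodeling scenario to baseline parameters
#'
#' Scales each named conductance / flux of `base` by the corresponding
#' scenario multiplier and the diffusion coefficient by `D_scale`. `base`
#' is not modified.
#'
#' @param base Named numeric vector as returned by [courtemanche_params()].
#' @param scenario A [scenario_config()].
#' @return A vector like `base` with the multipliers applied.
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  mult <- scenario$multipliers
  out <- base
  for (nm in setdiff(names(mult), "D_scale")) {
    if (nm %in% names(out)) out[nm] <- out[nm] * mult[nm]
  }
  if ("D_cm2_per_ms" %in% names(out))
    out["D_cm2_per_ms"] <- out["D_cm2_per_ms"] * mult["D_scale"]
  out
}

# the seven cell-level multipliers in the fixed order the C++ solver expects
scenario_mult_vector <- function(scenario) {
  m <- scenario$multipliers
  m[c("g_Na", "g_to", "g_CaL", "g_Kur", "g_K1", "k_NaCa_max", "sr_leak")]
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$name, "\n")
  changed <- x$multipliers[x$multipliers != 1]
  if (length(changed)) {
    for (nm in names(changed)) cat(sprintf("  %s = %g\n", nm, changed[nm]))
  } else cat("  (control: all multipliers 1)\n")
  invisible(x)
}
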