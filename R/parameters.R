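#' Kinetic parameter set for the LOS model
#'
#' Builds the full constant set of the leukotriene / 5-oxoETE synthesis
#' ("LOS") model: the catalytic-cycle constants of 5-lipoxygenase (5-LO),
#' cytosolic phospholipase A2 (cPLA2), glutathione peroxidase (GPx) and
#' 5-hydroxyeicosanoid dehydrogenase (HEDH), plus the first-order degradation
#' constants of 5-HETE (HT), LTA4 and 5-oxoETE.
#'
#' Internal canonical units are micromolar (uM) and minutes throughout.
#' Defaults are the published kinetic constants of the pathway model; the
#' four GPx constants that were never published (`GPx_full`, `Km_HP_GPx`,
#' `Km_GSH_GPx`, `K_HT_GPx`) carry documented calibration defaults and are
#' listed in `attr(, "calibrated")` (see [calibrate_gpx()]).
#'
#' @param ... named overrides of individual constants, e.g. `k_lo = 4600`.
#'   Unknown names are an error.
#' @return An object of class `los_parameters`: a named numeric vector with
#'   attributes `units` (named character) and `calibrated` (character vector
#'   of constants whose defaults come from calibration, not publication).
#' @examples
#' p <- los_parameters()
#' p[["k_lo"]]
#' p2 <- los_parameters(K_PF = 0.2)
#' @export
los_parameters <- function(...) {
  defaults <- c(
    # cPLA2
    Vmax_PLA2   = 450,      # uM/min, maximal AA release rate
    Km_PLA2_APC = 20,       # uM, phospholipid Michaelis constant
    K_Ca_PLA2   = 0.1,      # uM, Ca2+ activation constant
    # 5-LO catalytic cycle
    k_lo        = 4.6e3,    # 1/min, oxygenase turnover
    k_3         = 0.34e3,   # 1/(min uM), HP binding to ferric 5-LO
    k_LTAsyn    = 5.4e-4,   # 1/min, LTA4-synthase step
    k_ox        = 2.7e-4,   # 1/(min uM), Ca-independent oxidation by peroxide
    k_ox2       = 67.2,     # 1/(min uM), Ca-stimulated oxidation by peroxide
    k_r         = 2.54e-4,  # 1/min, Ca-independent spontaneous redox pair
    k_r2        = 4.4e-5,   # 1/min, Ca-stimulated spontaneous redox pair
    k_ing       = 16450,    # 1/min, redox-inhibitor-mediated reduction
    K_AA        = 10.7,     # uM, AA at the catalytic site
    K_AA_i      = 552,      # uM, AA at the regulatory (substrate-inhibition) site
    K_HT        = 0.54,     # uM, HT competitive inhibition
    K_PF        = 0.126,    # uM, non-redox inhibitor binding
    K_dz        = 36.6,     # uM, redox inhibitor binding
    K_d3        = 1.3e-4,   # -, HP binding equilibrium factor of the 5-LO:HP complex
    K_ox        = 100,      # uM, peroxide oxidation saturation constant
    K_r         = 5.8e-7,   # -, spontaneous reduction equilibrium factor
    K_2Ca       = 7110,     # uM, Ca2+ constant of rho1/rho2 and Delta_2Ca
    K_3Ca       = 14.4,     # uM, Ca2+ constant of rho7 and Delta_zCa
    # GPx
    kcat_GPx    = 0.489,    # 1/min, turnover
    Km_HP_GPx   = 23.3,     # uM, HP Michaelis constant (calibrated)
    Km_GSH_GPx  = 50,       # uM, GSH Michaelis constant (calibrated)
    K_HT_GPx    = 50,       # uM, HT product inhibition (calibrated)
    K_GSSG_GPx  = 0.072,    # uM, GSSG product inhibition
    # HEDH (reversible bi-bi ping-pong)
    k1_hedh     = 88.34,    # 1/min
    k2_hedh     = 1724,     # 1/min
    km1_hedh    = 31.5,     # 1/min
    km2_hedh    = 8.08,     # 1/min
    K_HT_hedh   = 0.332,    # uM
    K_NADP_hedh = 2.9,      # uM
    K_NADPH_hedh = 2.69,    # uM
    K_oxoETE_hedh = 1.67,   # uM
    # degradation sinks
    k_HTd       = 0.001,    # 1/min
    k_LTAd      = 0.07,     # 1/min
    k_oxoETEd   = 0.005     # 1/min
  )
  p <- .apply_overrides(defaults, list(...), "parameter")
  structure(p,
    units = .los_parameter_units(),
    calibrated = c("GPx_full", "Km_HP_GPx", "Km_GSH_GPx", "K_HT_GPx"),
    class = "los_parameters")
}

.los_parameter_units <- function() {
  c(Vmax_PLA2 = "uM/min", Km_PLA2_APC = "uM", K_Ca_PLA2 = "uM",
    k_lo = "1/min", k_3 = "1/(min uM)", k_LTAsyn = "1/min",
    k_ox = "1/(min uM)", k_ox2 = "1/(min uM)", k_r = "1/min", k_r2 = "1/min",
    k_ing = "1/min", K_AA = "uM", K_AA_i = "uM", K_HT = "uM", K_PF = "uM",
    K_dz = "uM", K_d3 = "-", K_ox = "uM", K_r = "-", K_2Ca = "uM",
    K_3Ca = "uM", kcat_GPx = "1/min", Km_HP_GPx = "uM", Km_GSH_GPx = "uM",
    K_HT_GPx = "uM", K_GSSG_GPx = "uM", k1_hedh = "1/min", k2_hedh = "1/min",
    km1_hedh = "1/min", km2_hedh = "1/min", K_HT_hedh = "uM",
    K_NADP_hedh = "uM", K_NADPH_hedh = "uM", K_oxoETE_hedh = "uM",
    k_HTd = "1/min", k_LTAd = "1/min", k_oxoETEd = "1/min")
}

#' Fixed-concentration environment (experimental scenario)
#'
#' The quantities held constant during a simulation: membrane phospholipid,
#' Ca2+, the glutathione and NADP(H) redox couples, the generic lipid
#' peroxide pool LOOH and its reduced product LOH, the two inhibitor doses
#' (Z, redox; PF, non-redox) and the three enzyme totals.
#'
#' @param ... named overrides, e.g. `LOOH = 10`. Unknown names are an error.
#' @return Object of class `los_environment`: named numeric vector (all uM)
#'   with a `units` attribute.
#' @examples
#' e <- los_environment(LOOH = 5, Z = 1)
#' @export
los_environment <- function(...) {
  defaults <- c(
    PL        = 40,    # uM phospholipid substrate of cPLA2
    Ca        = 1000,  # uM calcium
    GSH       = 5000,  # uM reduced glutathione
    GSSG      = 2500,  # uM oxidized glutathione
    NADPH     = 2000,  # uM
    NADP      = 1000,  # uM
    LOOH      = 0,     # uM generic (non-HP) lipid peroxide
    LOH       = 0,     # uM reduced peroxide product
    Z         = 0,     # uM redox inhibitor (zileuton)
    PF        = 0,     # uM non-redox inhibitor
    Fa        = 0.1,   # uM total active 5-LO
    GPx_full  = 6490,  # uM total GPx activity units (calibrated)
    HEDH_full = 0.1,   # uM total HEDH
    cpla2_scale = 1    # -, fraction of maximal cPLA2 activity in scenario
  )
  e <- .apply_overrides(defaults, list(...), "environment quantity")
  un <- stats::setNames(rep("uM", length(e)), names(e))
  un[["cpla2_scale"]] <- "-"
  structure(e, units = un, class = "los_environment")
}

.apply_overrides <- function(defaults, overrides, what) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all ", what, " overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown ", what, " name(s): ", paste(unknown, collapse = ", "),
        call. = FALSE)
    }
    defaults[nm] <- vapply(overrides, as.numeric, numeric(1))
  }
  defaults
}

#' Scenario registry
#'
#' Named experimental scenarios encoding published figure-legend conditions.
#' Pools are translated by the package conventions: a glutathione pool of
#' 10 mM with GSH 5 mM gives GSSG = (pool - GSH)/2 = 2.5 mM (two GSH per
#' GSSG); an NADP pool of 3 mM with NADPH 2 mM gives NADP = 1 mM.
#'
#' Available scenarios:
#' \describe{
#'   \item{`fig8`}{Cell-free GSH-threshold study: NADP pool 3 mM with NADPH
#'     2 mM, Ca 1 mM, 5-LO 0.1 uM, HEDH 0.1 uM; `PL` is swept by the caller
#'     (117/120/125 uM); GSH swept 0-10 mM.}
#'   \item{`fig10_table2_base`}{Base scenario of the inhibitor-potency grid:
#'     PL 40 uM, glutathione pool 10 mM with GSH 5 mM, otherwise as `fig8`.
#'     LOOH set per oxidative-stress level by the caller.}
#'   \item{`fig4_invitro`}{In-vitro AA sweep of the oxygenase rate: Ca
#'     300 uM, no cPLA2 feed (PL 0), no GPx/HEDH; AA supplied directly.}
#'   \item{`fig7_ca_sweep`}{Ca dependence of HP production: AA 20 uM
#'     supplied directly, PL 0, no GPx/HEDH.}
#' }
#'
#' @param name scenario identifier (see Details).
#' @param ... overrides applied on top of the scenario, e.g. `LOOH = 100`.
#' @return `los_environment` with a `provenance` attribute.
#' @examples
#' los_scenario("fig10_table2_base", LOOH = 5)
#' @export
los_scenario <- function(name, ...) {
  reg <- .los_scenario_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; available: ",
      paste(names(reg), collapse = ", "), call. = FALSE)
  }
  entry <- reg[[name]]
  e <- do.call(los_environment, c(entry$values, list(...)))
  attr(e, "provenance") <- entry$provenance
  e
}

.los_scenario_registry <- function() {
  list(
    fig8 = list(
      values = list(PL = 117, Ca = 1000, NADPH = 2000, NADP = 1000,
        GSH = 5000, GSSG = 2500, Fa = 0.1, HEDH_full = 0.1,
        cpla2_scale = 1.86e-3),
      provenance = "GSH-threshold study: NADP pool 3 mM (NADPH 2 mM), Ca 1 mM, 5-LO 0.1 uM, HEDH 0.1 uM; PL in {117,120,125} uM"),
    fig10_table2_base = list(
      values = list(PL = 40, Ca = 1000, GSH = 5000, GSSG = 2500,
        NADPH = 2000, NADP = 1000, Fa = 0.1, HEDH_full = 0.1, LOOH = 0,
        cpla2_scale = 1.86e-3),
      provenance = "Inhibitor study base: PL 40 uM, glutathione pool 10 mM (GSH 5 mM), NADP pool 3 mM (NADPH 2 mM), Ca 1 mM, 5-LO 0.1 uM, HEDH 0.1 uM"),
    fig4_invitro = list(
      values = list(PL = 0, Ca = 300, GSH = 0, GSSG = 0, NADPH = 0,
        NADP = 0, GPx_full = 0, HEDH_full = 0, Fa = 0.1),
      provenance = "In-vitro oxygenase assay: 0.3 mM Ca, AA supplied directly, no auxiliary enzymes"),
    fig7_ca_sweep = list(
      values = list(PL = 0, GSH = 0, GSSG = 0, NADPH = 0, NADP = 0,
        GPx_full = 0, HEDH_full = 0, Fa = 0.1, Ca = 0),
      provenance = "Ca dependence of HP production: 20 uM AA supplied directly; Ca swept")
  )
}

#' Validate a parameter set and environment
#'
#' Checks every structural invariant (rate constants non-negative, binding
#' and Michaelis constants strictly positive, concentrations non-negative)
#' and reports all violations. Validation never throws.
#'
#' @param p `los_parameters`
#' @param e `los_environment`
#' @return Object of class `los_validation`: character vector of violation
#'   messages (length 0 when everything holds), with `ok` attribute.
#' @examples
#' rep <- los_validate(los_parameters(), los_environment())
#' attr(rep, "ok")
#' @export
los_validate <- function(p = los_parameters(), e = los_environment()) {
  bad <- character(0)
  rate_constants <- c("Vmax_PLA2", "k_lo", "k_3", "k_LTAsyn", "k_ox",
    "k_ox2", "k_r", "k_r2", "k_ing", "kcat_GPx", "k1_hedh", "k2_hedh",
    "km1_hedh", "km2_hedh", "k_HTd", "k_LTAd", "k_oxoETEd", "K_r")
  binding_constants <- setdiff(names(p), rate_constants)
  for (nm in rate_constants) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      bad <- c(bad, paste0("rate constant ", nm, " must be >= 0 (got ",
        p[[nm]], ")"))
    }
  }
  for (nm in binding_constants) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      bad <- c(bad, paste0("binding/Michaelis constant ", nm,
        " must be > 0 (got ", p[[nm]], ")"))
    }
  }
  for (nm in names(e)) {
    if (!is.finite(e[[nm]]) || e[[nm]] < 0) {
      bad <- c(bad, paste0("concentration ", nm, " must be >= 0 (got ",
        e[[nm]], ")"))
    }
  }
  structure(bad, ok = length(bad) == 0L, class = "los_validation")
}

#' @export
print.los_validation <- function(x, ...) {
  if (attr(x, "ok")) {
    cat("los_validation: all invariants hold\n")
  } else {
    cat("los_validation:", length(x), "violation(s)\n")
    cat(paste0("  - ", unclass(x)), sep = "\n")
  }
  invisible(x)
}

#' @export
print.los_parameters <- function(x, ...) {
  cat("LOS model parameter set (", length(x), " constants; uM, min)\n",
    sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  cal <- attr(x, "calibrated")
  if (length(cal)) cat("calibrated (unpublished) defaults:",
    paste(cal, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.los_environment <- function(x, ...) {
  cat("LOS model environment (fixed concentrations, uM)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("provenance:", prov, "\n")
  invisible(x)
}

#' Write / read parameter and environment configuration
#'
#' Flat-key YAML or JSON serialization. Reading applies the file's entries as
#' overrides on top of the defaults; unknown keys are an error (no silent
#' typo absorption).
#'
#' @param p `los_parameters`
#' @param e `los_environment`
#' @param path output/input file; format chosen by extension
#'   (`.json`, `.yaml`/`.yml`).
#' @return `write_los_config()` returns `path` invisibly; `read_los_config()`
#'   returns `list(parameters =, environment =)`.
#' @export
write_los_config <- function(p, e, path) {
  payload <- list(
    units = "uM, min",
    parameters = as.list(stats::setNames(as.numeric(p), names(p))),
    environment = as.list(stats::setNames(as.numeric(e), names(e))))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' @rdname write_los_config
#' @export
read_los_config <- function(path) {
  payload <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  list(
    parameters = do.call(los_parameters, as.list(payload$parameters)),
    environment = do.call(los_environment, as.list(payload$environment)))
}
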