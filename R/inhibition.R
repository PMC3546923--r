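#' Dose-response protocol: baseline then inhibited steady states
#'
#' The inhibitor protocol mirrors the study design the potency tables encode:
#' the uninhibited system is first run to steady state (all five species
#' dynamic), establishing the poised arachidonic-acid level set by the
#' phospholipid supply; the inhibitor is then added and the new steady state
#' of the downstream species (HP, HT, LTA4, oxoETE) is computed with AA held
#' at that poised level. Clamping AA reflects that the cellular AA level is
#' a property of the stimulus (PL, cPLA2), not of the 5-LO branch: without
#' it, mass action would let AA rise until 5-LO throughput is fully
#' restored, and no inhibitor could ever reduce total product flux.
#'
#' @param e `los_environment` (inhibitor fields are overridden per dose).
#' @param p `los_parameters`.
#' @return The baseline `los_steady` with an `aa_poised` element.
#' @keywords internal
.inhibition_baseline <- function(e, p) {
  e0 <- e
  e0[["Z"]] <- 0
  e0[["PF"]] <- 0
  ss <- los_steady_state(e0, p)
  if (!ss$converged) {
    stop("baseline (dose 0) steady state did not converge; residual ",
      format(ss$residual_norm, digits = 3), " uM/min", call. = FALSE)
  }
  ss
}

.inhibited_steady <- function(inhibitor, dose, base_state, e, p) {
  e1 <- e
  e1[[inhibitor]] <- dose
  los_steady_state(e1, p, init = base_state, clamp = "AA")
}

#' Percent inhibition of a steady-state output
#'
#' `100 * (1 - X_st(dose) / X_st(0))` for `X` = LTA4 or oxoETE, using
#' converged steady states under the AA-poised protocol (see
#' [dose_response()]). The value may be negative — redox inhibitors can
#' *increase* 5-oxoETE production under oxidative stress — and is reported
#' as computed, never clamped.
#'
#' @param inhibitor `"Z"` (redox, zileuton-like) or `"PF"` (non-redox,
#'   competitive).
#' @param dose inhibitor concentration, uM.
#' @param species `"LTA4"` or `"oxoETE"`.
#' @param e `los_environment`, the scenario (its `LOOH` sets the
#'   oxidative-stress level).
#' @param p `los_parameters`.
#' @param baseline optional precomputed result of the uninhibited run
#'   (recycled across doses by [dose_response()]).
#' @return percent inhibition (scalar).
#' @examples
#' \donttest{
#' e <- los_scenario("fig10_table2_base", LOOH = 5)
#' inhibition_percent("PF", 0.126, "LTA4", e, los_parameters())
#' }
#' @export
inhibition_percent <- function(inhibitor = c("Z", "PF"), dose,
                               species = c("LTA4", "oxoETE"),
                               e, p, baseline = NULL) {
  inhibitor <- match.arg(inhibitor)
  species <- match.arg(species)
  if (is.null(baseline)) baseline <- .inhibition_baseline(e, p)
  x0 <- baseline$state[[species]]
  if (x0 <= 0) {
    stop("baseline steady-state ", species, " is zero; percent inhibition ",
      "is undefined", call. = FALSE)
  }
  if (dose == 0) return(0)
  ss <- .inhibited_steady(inhibitor, dose, baseline$state, e, p)
  100 * (1 - ss$state[[species]] / x0)
}

#' Full dose-response curve
#'
#' Scans a log-spaced dose grid (default 1 nM - 1 mM, 25 points) and
#' returns the inhibition curve for one inhibitor and one output species.
#'
#' @inheritParams inhibition_percent
#' @param doses dose grid, uM (increasing).
#' @return `los_dose_response`: data.frame with `dose_uM` and
#'   `inhibition_pct`, plus attributes `inhibitor`, `species`,
#'   `environment`, `baseline`.
#' @export
dose_response <- function(inhibitor = c("Z", "PF"),
                          species = c("LTA4", "oxoETE"), e, p,
                          doses = 10^seq(-3, 3, length.out = 25)) {
  inhibitor <- match.arg(inhibitor)
  species <- match.arg(species)
  baseline <- .inhibition_baseline(e, p)
  pct <- vapply(doses, function(d) {
    inhibition_percent(inhibitor, d, species, e, p, baseline = baseline)
  }, numeric(1))
  structure(
    data.frame(dose_uM = doses, inhibition_pct = pct),
    inhibitor = inhibitor, species = species, environment = e,
    baseline = baseline,
    class = c("los_dose_response", "data.frame"))
}

#' Inhibitory potency (IC50, IC80, ...)
#'
#' Finds the dose at which percent inhibition crosses `level_pct`, by
#' log-dose bisection to `|Inh% - level| <= 0.1`. A coarse log-spaced
#' pre-scan brackets the crossing; if the curve is non-monotone the lowest
#' crossing is returned and flagged (`multiple = TRUE`). When the curve
#' never reaches the level inside the bracket an error reports the curve
#' maximum.
#'
#' @inheritParams inhibition_percent
#' @param level_pct target inhibition level (50 for IC50, 80 for IC80).
#' @param bracket numeric length-2, dose search interval in uM.
#' @param n_scan points in the bracketing pre-scan.
#' @return dose in uM with attributes `nM` (same value in nM), `level_pct`,
#'   `multiple` (logical: non-monotone curve with several crossings).
#' @examples
#' \donttest{
#' e <- los_scenario("fig10_table2_base", LOOH = 5)
#' ic50 <- find_icxx(50, "PF", "LTA4", e, los_parameters())
#' attr(ic50, "nM")
#' }
#' @export
find_icxx <- function(level_pct, inhibitor = c("Z", "PF"),
                      species = c("LTA4", "oxoETE"), e, p,
                      bracket = c(1e-3, 1e3), n_scan = 13) {
  inhibitor <- match.arg(inhibitor)
  species <- match.arg(species)
  stopifnot(length(bracket) == 2, bracket[1] > 0, bracket[2] > bracket[1])
  baseline <- .inhibition_baseline(e, p)
  f <- function(d) {
    inhibition_percent(inhibitor, d, species, e, p, baseline = baseline)
  }
  .icxx_search(f, level_pct, bracket, n_scan)
}

# log-dose bracketing pre-scan + bisection on an arbitrary inhibition curve;
# shared by find_icxx and testable against closed-form curves
.icxx_search <- function(f, level_pct, bracket, n_scan = 13) {
  grid <- 10^seq(log10(bracket[1]), log10(bracket[2]), length.out = n_scan)
  vals <- vapply(grid, f, numeric(1))
  above <- vals >= level_pct
  if (!any(above)) {
    stop("inhibition never reaches ", level_pct, "% within [",
      bracket[1], ", ", bracket[2], "] uM; curve maximum is ",
      signif(max(vals), 4), "% at ", signif(grid[which.max(vals)], 4),
      " uM", call. = FALSE)
  }
  crossings <- which(!above[-length(above)] & above[-1])
  multiple <- length(crossings) > 1
  if (above[1]) {
    # already above the level at the smallest scanned dose
    lo <- bracket[1] * 1e-3
    hi <- grid[1]
    if (f(lo) >= level_pct) {
      warning("inhibition exceeds ", level_pct, "% even at ", lo,
        " uM; returning bracket floor", call. = FALSE)
      return(structure(lo, nM = lo * 1e3, level_pct = level_pct,
        multiple = multiple))
    }
  } else {
    i <- crossings[1]
    lo <- grid[i]
    hi <- grid[i + 1]
  }
  for (iter in seq_len(60)) {
    mid <- sqrt(lo * hi)
    v <- f(mid)
    if (abs(v - level_pct) <= 0.1) {
      return(structure(mid, nM = mid * 1e3, level_pct = level_pct,
        multiple = multiple))
    }
    if (v < level_pct) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  structure(mid, nM = mid * 1e3, level_pct = level_pct, multiple = multiple)
}

#' Inhibitor potency grid across oxidative-stress levels
#'
#' IC50 (and optionally IC80) for each combination of lipid-peroxide level,
#' inhibitor and output species — the simulated analogue of an
#' inhibitor-potency table at increasing oxidative stress. Cells whose
#' dose-response never crosses the level are reported as `NA` with the
#' failure reason in the `flags` attribute rather than aborting the grid.
#'
#' @param loohs lipid peroxide (LOOH) levels, uM.
#' @param e_base base environment (its LOOH field is overridden per row).
#' @param p `los_parameters`.
#' @param inhibitors,species combinations to scan.
#' @param levels inhibition levels to extract, e.g. `c(50, 80)`.
#' @param path optional CSV output path (columns `LOOH_uM, inhibitor,
#'   species, IC50_nM, IC80_nM`, units in the header row comment).
#' @return `los_potency_table`: data.frame keyed by (LOOH_uM, inhibitor,
#'   species) with one `IC<level>_nM` column per level.
#' @examples
#' \donttest{
#' tab <- potency_grid(c(0, 5), los_scenario("fig10_table2_base"),
#'   los_parameters(), levels = 50)
#' }
#' @export
potency_grid <- function(loohs = c(0, 5, 10, 100),
                         e_base = los_scenario("fig10_table2_base"),
                         p = los_parameters(),
                         inhibitors = c("Z", "PF"),
                         species = c("LTA4", "oxoETE"),
                         levels = c(50, 80), path = NULL) {
  stopifnot(length(loohs) >= 1)
  rows <- expand.grid(LOOH_uM = loohs, inhibitor = inhibitors,
    species = species, stringsAsFactors = FALSE)
  flags <- character(0)
  for (lv in levels) rows[[paste0("IC", lv, "_nM")]] <- NA_real_
  for (r in seq_len(nrow(rows))) {
    e <- e_base
    e[["LOOH"]] <- rows$LOOH_uM[r]
    for (lv in levels) {
      val <- tryCatch(
        find_icxx(lv, rows$inhibitor[r], rows$species[r], e, p),
        error = function(err) {
          flags <<- c(flags, paste0("IC", lv, " ", rows$inhibitor[r], "/",
            rows$species[r], " LOOH=", rows$LOOH_uM[r], ": ",
            conditionMessage(err)))
          NA_real_
        })
      rows[r, paste0("IC", lv, "_nM")] <-
        if (is.na(val[1])) NA_real_ else attr(val, "nM")
    }
  }
  out <- structure(rows, flags = flags,
    class = c("los_potency_table", "data.frame"))
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  }
  out
}

#' @export
print.los_potency_table <- function(x, ...) {
  cat("Inhibitor potency grid (IC values in nM)\n")
  print(as.data.frame(x), digits = 4)
  fl <- attr(x, "flags")
  if (length(fl)) cat("flagged cells:\n", paste(" -", fl, collapse = "\n"),
    "\n")
  invisible(x)
}
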