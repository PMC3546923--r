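#' Figure-scenario regression suite
#'
#' Re-runs the encoded experimental scenarios and checks the qualitative
#' behaviors the model is supposed to show:
#' \describe{
#' \item{substrate_inhibition}{in-vitro AA sweep of the oxygenase rate has
#'   a maximum strictly inside (1, 300) uM (substrate inhibition via the
#'   regulatory site).}
#' \item{ca_ec50}{the Ca2+ half-activation of the HP production rate at
#'   20 uM AA is at or below 3 uM.}
#' \item{gsh_threshold}{in the cell-free scenario, raising the glutathione
#'   pool's reduced fraction from fully oxidized to fully reduced
#'   suppresses total 5-LO metabolites (HP+HT+LTA4) much more strongly at
#'   the lower phospholipid supply (PL 117) than at the higher one (PL
#'   125).}
#' \item{peroxide_consumption}{with 10 uM peroxide present, the redox
#'   inhibitor (10 uM) visibly consumes the peroxide pool by 30 min while
#'   the non-redox inhibitor's trajectory coincides with the uninhibited
#'   one within 1\%.}
#' }
#'
#' @param p `los_parameters`.
#' @param seed_hp trace peroxide, uM, present at the start of the in-vitro
#'   rate assays (a rate cannot be measured at exactly zero product; the
#'   redox state is undefined without any peroxide).
#' @return data.frame with one row per check: `check`, `pass`, `detail`.
#' @export
figure_regression_suite <- function(p = los_parameters(), seed_hp = 0.01) {
  out <- list()

  # substrate inhibition of the oxygenase rate
  e4 <- los_scenario("fig4_invitro")
  aa <- seq(1, 300, by = 1)
  v4 <- vapply(aa, function(a) {
    five_lo_rates(los_state(AA = a, HP = seed_hp), e4, p)$V_AAcons
  }, numeric(1))
  i_max <- which.max(v4)
  pass4 <- i_max > 1 && i_max < length(aa)
  out$substrate_inhibition <- list(pass = pass4,
    detail = sprintf("argmax at AA = %g uM, rate %.3g uM/min", aa[i_max],
      v4[i_max]))

  # Ca half-activation of HP production
  cas <- 10^seq(-2, 3, length.out = 121)
  v7 <- vapply(cas, function(ca) {
    e7 <- los_scenario("fig7_ca_sweep", Ca = ca)
    r <- five_lo_rates(los_state(AA = 20, HP = seed_hp), e7, p)
    r$V_HPsyn
  }, numeric(1))
  v_max <- max(v7)
  ec50 <- cas[which(v7 >= v_max / 2)[1]]
  out$ca_ec50 <- list(pass = is.finite(ec50) && ec50 <= 3,
    detail = sprintf("EC50 = %.3g uM (max rate %.3g uM/min at Ca = %.3g)",
      ec50, v_max, cas[which.max(v7)]))

  # GSH threshold at two phospholipid supplies
  suppression <- function(pl) {
    met <- function(gsh) {
      e <- los_scenario("fig8", PL = pl, GSH = gsh, GSSG = (10000 - gsh) / 2)
      ss <- los_steady_state(e, p)
      sum(ss$state[c("HP", "HT", "LTA4")])
    }
    lo <- met(0)
    hi <- met(10000)
    100 * (1 - hi / lo)
  }
  sup117 <- suppression(117)
  sup125 <- suppression(125)
  out$gsh_threshold <- list(pass = sup117 > 50 && sup125 < 20,
    detail = sprintf("suppression %.1f%% at PL 117 vs %.1f%% at PL 125",
      sup117, sup125))

  # peroxide consumption ordering under the two inhibitor classes
  hp30 <- function(z, pf) {
    e <- los_scenario("fig10_table2_base", Z = z, PF = pf)
    tc <- los_simulate(e, p, times = c(0, 30), init = los_state(HP = 10))
    tc$HP[2]
  }
  hp_none <- hp30(0, 0)
  hp_z <- hp30(10, 0)
  hp_pf <- hp30(0, 10)
  pass10 <- hp_z < hp_none && abs(hp_pf - hp_none) / hp_none < 0.01
  out$peroxide_consumption <- list(pass = pass10,
    detail = sprintf("HP(30 min): none %.3g, Z %.3g, PF %.3g uM",
      hp_none, hp_z, hp_pf))

  data.frame(check = names(out),
    pass = vapply(out, `[[`, logical(1), "pass"),
    detail = vapply(out, `[[`, character(1), "detail"),
    row.names = NULL)
}

#' Command-line interface
#'
#' A thin shell entry point over the package functions; installed as
#' `inst/cli/losmodel.R` and invoked as
#' `Rscript -e 'losmodel::run_cli()' <subcommand> [options]` or via the
#' wrapper script. Subcommands:
#' \describe{
#'   \item{simulate}{`--scenario NAME --t-end MIN [--out DIR]`: time course
#'     CSV.}
#'   \item{steady}{`--scenario NAME [--out DIR]`: steady state JSON.}
#'   \item{dose-response}{`--scenario NAME --inhibitor Z|PF --species
#'     LTA4|oxoETE [--looh UM] [--out DIR]`: curve CSV.}
#'   \item{table2}{`[--out DIR]`: the full potency grid CSV (4 peroxide
#'     levels x 2 inhibitors x 2 species, IC50 and IC80).}
#'   \item{export-sbml}{`[--scenario NAME] [--out DIR]`: SBML L3 file.}
#'   \item{calibrate-gpx}{`[--max-eval N] [--out DIR]`: rerun the GPx
#'     calibration and write the tuned values.}
#'   \item{fit-demo}{`[--seed N] [--out DIR]`: synthetic-data parameter
#'     recovery demonstration.}
#' }
#' Every artifact is written with a provenance JSON (config echo, package
#' version, seed).
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success). Parse or convergence
#'   failures signal conditions; the wrapper script converts them to a
#'   non-zero exit.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    cat("usage: losmodel <simulate|steady|dose-response|table2|export-sbml|",
      "calibrate-gpx|fit-demo> [--key value ...]\n", sep = "")
    return(invisible(if (length(argv)) 0L else 1L))
  }
  cmd <- argv[1]
  opts <- .parse_kv(argv[-1])
  out_dir <- opts[["out"]] %||chr% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(opts[["seed"]] %||chr% "1")
  scen <- opts[["scenario"]] %||chr% "fig10_table2_base"
  p <- los_parameters()
  provenance <- list(command = cmd, options = opts,
    package_version = as.character(utils::packageVersion("losmodel")),
    seed = seed, units = "uM, min; potencies nM")

  status <- switch(cmd,
    "simulate" = {
      e <- los_scenario(scen)
      t_end <- as.numeric(opts[["t-end"]] %||chr% "60")
      tc <- los_simulate(e, p, t_end = t_end)
      timecourse_tidy(tc, file.path(out_dir, "timecourse.csv"))
      0L
    },
    "steady" = {
      e <- los_scenario(scen)
      ss <- los_steady_state(e, p)
      jsonlite::write_json(list(state = as.list(ss$state),
        residual_norm = ss$residual_norm, converged = ss$converged,
        method = ss$method, units = "uM"),
        file.path(out_dir, "steady_state.json"), auto_unbox = TRUE,
        digits = NA)
      if (ss$converged) 0L else 2L
    },
    "dose-response" = {
      e <- los_scenario(scen,
        LOOH = as.numeric(opts[["looh"]] %||chr% "0"))
      dr <- dose_response(opts[["inhibitor"]] %||chr% "Z",
        opts[["species"]] %||chr% "LTA4", e, p)
      utils::write.csv(as.data.frame(dr),
        file.path(out_dir, "dose_response.csv"), row.names = FALSE)
      0L
    },
    "table2" = {
      tab <- potency_grid(path = file.path(out_dir, "table2.csv"))
      flagged <- length(attr(tab, "flags")) > 0
      if (flagged && is.null(opts[["allow-partial"]])) 3L else 0L
    },
    "export-sbml" = {
      e <- los_scenario(scen)
      export_sbml(p, e, file.path(out_dir, "los_model.xml"))
      0L
    },
    "calibrate-gpx" = {
      res <- calibrate_gpx(
        max_eval = as.integer(opts[["max-eval"]] %||chr% "60"))
      jsonlite::write_json(list(par = as.list(res$par),
        objective = res$objective, failed = res$calibration_failed),
        file.path(out_dir, "gpx_calibration.json"), auto_unbox = TRUE,
        digits = NA)
      if (res$calibration_failed) 4L else 0L
    },
    "fit-demo" = {
      design <- lapply(c(2, 5, 10, 20, 50, 100, 150, 200, 250, 300),
        function(a) list(state = list(AA = a, HP = 0.01)))
      rec <- recover_parameters(
        c(k_lo = 4.6e3, K_AA = 10.7), "V_AAcons", design,
        noise_sd = 0, seed = seed,
        e = los_scenario("fig4_invitro"))
      jsonlite::write_json(list(true = as.list(rec$true),
        estimate = as.list(rec$estimate),
        rel_error = as.list(rec$rel_error)),
        file.path(out_dir, "fit_demo.json"), auto_unbox = TRUE, digits = NA)
      0L
    },
    {
      message("unknown subcommand '", cmd, "'")
      NA_integer_
    })
  if (is.na(status)) return(invisible(1L))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(status)
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

.parse_kv <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument '", a, "'", call. = FALSE)
    }
    key <- substring(a, 3)
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}
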