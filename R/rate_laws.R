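#' State vector constructor
#'
#' The five dynamic species of the LOS model, in uM: arachidonic acid (AA),
#' 5-HPETE (HP), 5-HETE (HT), leukotriene A4 (LTA4) and 5-oxoETE (oxoETE).
#'
#' @param AA,HP,HT,LTA4,oxoETE concentrations, uM.
#' @return Named numeric vector of length 5.
#' @export
los_state <- function(AA = 0, HP = 0, HT = 0, LTA4 = 0, oxoETE = 0) {
  c(AA = AA, HP = HP, HT = HT, LTA4 = LTA4, oxoETE = oxoETE)
}

#' Algebraic terms of the reduced 5-LO catalytic cycle
#'
#' The quasi-steady-state reduction of the 5-LO catalytic cycle collapses
#' the 26 enzyme states into three pools — ferric (active), the 5-LO:HP
#' complex, and ferrous (inactive) — whose relative weights are the
#' dimensionless terms returned here:
#'
#' \describe{
#' \item{`Delta_Z`}{`1 + Z/K_dz`, redox-inhibitor occupancy of the catalytic
#'   site.}
#' \item{`Delta_2Ca`}{`1 + Ca/K_2Ca`, Ca occupancy of the non-Z states.}
#' \item{`Delta_zCa`}{`Delta_Z * (1 + Ca/K_3Ca)`, joint Z/Ca occupancy (the
#'   factorized identity holds to machine precision).}
#' \item{`delta_HP`}{`1 + AA/K_AA_i`, regulatory-site (substrate-inhibition)
#'   partition.}
#' \item{`delta_L`}{ferric-pool weight:
#'   `1 + (AA/K_AA_i)/Delta_Z + delta_HP*(AA/K_AA + HT/K_HT + PF/K_PF)/Delta_Z`.}
#' \item{`Delta_HP`}{5-LO:HP complex weight,
#'   `delta_HP*(k_lo*AA/K_AA + k_3*K_d3*HP*delta_HP) /
#'    (Delta_Z*(k_LTAsyn + k_3*delta_HP))`: oxygenase influx plus HP
#'   rebinding (rate constant `k_3*K_d3`) balanced against LTA4-synthase
#'   exit and HP release (rate `k_3`). `K_d3` is the dimensionless binding
#'   equilibrium factor: rebinding of free HP is weak relative to release,
#'   so endogenously generated HP (the oxygenase path) is the preferred
#'   LTA4-synthase substrate.}
#' \item{`Delta_redox`}{ferrous-pool weight,
#'   `(Delta_2Ca/Delta_zCa) * (rho2 + (rho1/K_ox)*(LOH + HT) +
#'    rho7*Z/K_dz) / (rho2*K_r + rho1*(LOOH + HP))`: reduction of the
#'   ferric enzyme (spontaneous, by reduced lipid products, and by the
#'   redox inhibitor) balanced against oxidation of the ferrous enzyme
#'   (spontaneous, scaled by the equilibrium factor `K_r`, plus lipid
#'   peroxides). The resting enzyme at zero peroxide is almost entirely
#'   ferrous (`1/K_r`); peroxides and Ca2+ (through `k_ox2`) drive it into
#'   the active ferric state.}
#' \item{`rho1`}{`k_ox + k_ox2*Ca/K_2Ca`, peroxide oxidation rate, 1/(min uM).}
#' \item{`rho2`}{`k_r + k_r2*Ca/K_2Ca`, spontaneous redox rate, 1/min.}
#' \item{`rho7`}{`k_ing*(1 + Ca/K_2Ca)`, inhibitor-mediated reduction,
#'   1/min. Its Ca modulation follows the rate-constant site (`K_2Ca`),
#'   while the Z-state occupancy factor `Delta_zCa` carries the uM-scale
#'   binding constant `K_3Ca`; were the two shared, the Ca factors would
#'   cancel exactly in the redox-inhibitor term and zileuton-class potency
#'   would be overestimated ~60-fold at millimolar Ca.}
#' \item{`Delta_tot`}{`delta_L + Delta_HP + Delta_redox`, total partition.}
#' }
#'
#' @param s state vector from [los_state()].
#' @param e `los_environment`.
#' @param p `los_parameters`.
#' @return Named list with the eleven terms above.
#' @export
five_lo_terms <- function(s, e, p) {
  AA <- s[["AA"]]; HP <- s[["HP"]]; HT <- s[["HT"]]
  Ca <- e[["Ca"]]; Z <- e[["Z"]]; PF <- e[["PF"]]
  LOOH <- e[["LOOH"]]; LOH <- e[["LOH"]]

  Delta_Z   <- 1 + Z / p[["K_dz"]]
  Delta_2Ca <- 1 + Ca / p[["K_2Ca"]]
  Delta_zCa <- Delta_Z * (1 + Ca / p[["K_3Ca"]])

  rho1 <- p[["k_ox"]] + p[["k_ox2"]] * Ca / p[["K_2Ca"]]
  rho2 <- p[["k_r"]]  + p[["k_r2"]]  * Ca / p[["K_2Ca"]]
  rho7 <- p[["k_ing"]] * (1 + Ca / p[["K_2Ca"]])

  delta_HP <- 1 + AA / p[["K_AA_i"]]
  delta_L  <- 1 + (AA / p[["K_AA_i"]]) / Delta_Z +
    delta_HP * (AA / p[["K_AA"]] + HT / p[["K_HT"]] + PF / p[["K_PF"]]) /
      Delta_Z

  Delta_HP <- delta_HP *
    (p[["k_lo"]] * AA / p[["K_AA"]] +
      p[["k_3"]] * p[["K_d3"]] * HP * delta_HP) /
    (Delta_Z * (p[["k_LTAsyn"]] + p[["k_3"]] * delta_HP))

  Delta_redox <- (Delta_2Ca / Delta_zCa) *
    (rho2 + (rho1 / p[["K_ox"]]) * (LOH + HT) + rho7 * Z / p[["K_dz"]]) /
    (rho2 * p[["K_r"]] + rho1 * (LOOH + HP))

  Delta_tot <- delta_L + Delta_HP + Delta_redox

  list(Delta_tot = Delta_tot, Delta_HP = Delta_HP, delta_L = delta_L,
    delta_HP = delta_HP, Delta_redox = Delta_redox,
    rho1 = rho1, rho2 = rho2, rho7 = rho7,
    Delta_Z = Delta_Z, Delta_zCa = Delta_zCa, Delta_2Ca = Delta_2Ca)
}

#' 5-LO reaction fluxes
#'
#' The five fluxes of the reduced 5-LO catalytic cycle, uM/min:
#' oxygenase AA consumption `V_AAcons`, LTA4-synthase `V_LTAsyn`, net HP
#' release `V_HPsyn` (negative when exogenous HP rebinds faster than the
#' complex releases it), and the pseudo-peroxidase pair `V_HPcons_pseudo`
#' (HP reduced to HT by ferrous 5-LO) and `V_LOOHcons_pseudo` (generic
#' peroxide reduced to LOH). The stoichiometric identities
#' `V_HTsyn_pseudo == V_HPcons_pseudo`, `V_LOHsyn_pseudo == V_LOOHcons_pseudo`
#' and the carbon balance `V_AAcons == V_LTAsyn + V_HPsyn` hold exactly.
#' The pseudo-peroxidase fluxes are `rho1*(Fa/Delta_tot)*(HP*Delta_redox -
#' HT/K_ox)` and `rho1*(Fa/Delta_tot)*(LOOH*Delta_redox - LOH/K_ox)`:
#' ferrous enzyme reduces the peroxide (forward), while the reduced
#' products drive the reverse reduction of the ferric enzyme; the bracket
#' may go negative when products accumulate, and is reported as computed.
#'
#' @inheritParams five_lo_terms
#' @param terms optional precomputed [five_lo_terms()] result.
#' @return Named list of five fluxes (uM/min).
#' @export
five_lo_rates <- function(s, e, p, terms = five_lo_terms(s, e, p)) {
  AA <- s[["AA"]]; HP <- s[["HP"]]; HT <- s[["HT"]]
  LOOH <- e[["LOOH"]]; LOH <- e[["LOH"]]
  Fa <- e[["Fa"]]
  scale <- Fa / terms$Delta_tot

  V_AAcons <- p[["k_lo"]] * (AA / p[["K_AA"]]) / terms$Delta_Z * scale
  V_LTAsyn <- p[["k_LTAsyn"]] * terms$Delta_HP / terms$delta_HP * scale
  V_HPsyn  <- p[["k_3"]] * scale *
    (terms$Delta_HP - p[["K_d3"]] * HP * terms$delta_HP / terms$Delta_Z)
  V_HPcons_pseudo <- terms$rho1 * scale *
    (HP * terms$Delta_redox - HT / p[["K_ox"]])
  V_LOOHcons_pseudo <- terms$rho1 * scale *
    (LOOH * terms$Delta_redox - LOH / p[["K_ox"]])

  list(V_AAcons = V_AAcons, V_LTAsyn = V_LTAsyn, V_HPsyn = V_HPsyn,
    V_HPcons_pseudo = V_HPcons_pseudo,
    V_HTsyn_pseudo = V_HPcons_pseudo,
    V_LOOHcons_pseudo = V_LOOHcons_pseudo,
    V_LOHsyn_pseudo = V_LOOHcons_pseudo)
}

#' cPLA2 rate
#'
#' Ca2+-activated release of arachidonic acid from membrane phospholipid:
#' `V = cpla2_scale * Vmax_PLA2 * Ca/(K_Ca_PLA2 + Ca) * PL/(Km_PLA2_APC + PL)`.
#' `Vmax_PLA2` is the fully activated maximal rate; the environment's
#' `cpla2_scale` (default 1) expresses the fraction of that activity present
#' in a scenario (the packaged cellular scenarios use the calibrated value
#' 1.86e-3, an effective ceiling of ~840 nM/min, which places the AA influx
#' on the scale the downstream pathway can carry).
#'
#' @inheritParams five_lo_terms
#' @return flux, uM/min.
#' @export
cpla2_rate <- function(s, e, p) {
  Ca <- e[["Ca"]]; PL <- e[["PL"]]
  e[["cpla2_scale"]] * p[["Vmax_PLA2"]] * (Ca / (p[["K_Ca_PLA2"]] + Ca)) *
    PL / (p[["Km_PLA2_APC"]] + PL)
}

#' Glutathione peroxidase rate
#'
#' Ping-pong reduction of HP to HT consuming two GSH, with HT and GSSG
#' product inhibition; linear in the enzyme total `GPx_full`.
#'
#' @inheritParams five_lo_terms
#' @return flux, uM/min.
#' @export
gpx_rate <- function(s, e, p) {
  HP <- s[["HP"]]; HT <- s[["HT"]]
  GSH <- e[["GSH"]]; GSSG <- e[["GSSG"]]
  hp <- HP / p[["Km_HP_GPx"]]
  gsh <- GSH / p[["Km_GSH_GPx"]]
  B <- p[["kcat_GPx"]] * hp * gsh * gsh
  A <- hp * (1 + HT / p[["K_HT_GPx"]]) +
    gsh * gsh * (1 + GSSG / p[["K_GSSG_GPx"]]) +
    gsh * gsh * hp
  if (A == 0) return(0)
  e[["GPx_full"]] * B / A
}

#' HEDH rate
#'
#' Reversible bi-bi ping-pong oxidation of HT to 5-oxoETE with NADP+ as the
#' second substrate. Positive flux is HT -> oxoETE; the sign follows the
#' numerator `k1*k2*HT*NADP/(K_HT*K_NADP) - k-1*k-2*oxoETE*NADPH/(K_oxo*K_NADPH)`.
#'
#' @inheritParams five_lo_terms
#' @return signed flux, uM/min.
#' @export
hedh_rate <- function(s, e, p) {
  HT <- s[["HT"]]; oxo <- s[["oxoETE"]]
  NADP <- e[["NADP"]]; NADPH <- e[["NADPH"]]
  ht <- HT / p[["K_HT_hedh"]]
  nadp <- NADP / p[["K_NADP_hedh"]]
  nadph <- NADPH / p[["K_NADPH_hedh"]]
  ox <- oxo / p[["K_oxoETE_hedh"]]
  B <- p[["k1_hedh"]] * p[["k2_hedh"]] * ht * nadp -
    p[["km1_hedh"]] * p[["km2_hedh"]] * ox * nadph
  A <- (1 + nadp + ox) * p[["k1_hedh"]] * ht + p[["km2_hedh"]] * nadph +
    (1 + ht + nadph) * p[["km1_hedh"]] * ox + p[["k2_hedh"]] * nadp
  if (A == 0) return(0)
  e[["HEDH_full"]] * B / A
}

#' First-order degradation fluxes
#'
#' Mass-action sinks for HT, LTA4 and oxoETE.
#'
#' @inheritParams five_lo_terms
#' @return Named list `V_HTd`, `V_LTAd`, `V_oxoETEd` (uM/min).
#' @export
degradation_rates <- function(s, p) {
  list(V_HTd = p[["k_HTd"]] * s[["HT"]],
    V_LTAd = p[["k_LTAd"]] * s[["LTA4"]],
    V_oxoETEd = p[["k_oxoETEd"]] * s[["oxoETE"]])
}

#' All reaction fluxes of the LOS model
#'
#' Evaluates every rate law at one state: cPLA2, the five 5-LO fluxes, GPx,
#' HEDH and the three degradation sinks.
#'
#' @inheritParams five_lo_terms
#' @return Named list of fluxes (uM/min).
#' @export
los_rates <- function(s, e, p) {
  c(list(V_AA_PLA2 = cpla2_rate(s, e, p)),
    five_lo_rates(s, e, p),
    list(V_GPx = gpx_rate(s, e, p), V_HEDH = hedh_rate(s, e, p)),
    degradation_rates(s, p))
}
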