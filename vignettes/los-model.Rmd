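---
title: "The LOS model: kinetics of leukotriene A4 and 5-oxoETE synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LOS model: kinetics of leukotriene A4 and 5-oxoETE synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(losmodel)
```

## The pathway and the model

5-lipoxygenase (5-LO) converts arachidonic acid (AA) into 5-HPETE (here
HP), the hydroperoxide precursor of leukotriene A4 (LTA4). HP is reduced to
5-HETE (HT) either by glutathione peroxidase (GPx) or by the
pseudo-peroxidase activity of 5-LO itself, and HT is oxidized by
5-hydroxyeicosanoid dehydrogenase (HEDH) to 5-oxoETE, a potent eosinophil
chemoattractant. `losmodel` implements a quasi-steady-state (QSSA) kinetic
model of this pathway with five dynamic species — AA, HP, HT, LTA4 and
5-oxoETE, all in µM — driven by a Ca²⁺-activated cPLA2 source of AA and
drained by first-order degradation of HT, LTA4 and 5-oxoETE:

$$\begin{aligned}
\dot{AA} &= V_{PLA2} - V_{AAcons}\\
\dot{HP} &= V_{HPsyn} - V_{HPcons}^{pp} - V_{GPx}\\
\dot{HT} &= V_{HPcons}^{pp} + V_{GPx} - V_{HEDH} - k_{HTd}\,HT\\
\dot{LTA4} &= V_{LTAsyn} - k_{LTAd}\,LTA4\\
\dot{oxoETE} &= V_{HEDH} - k_{oxoETEd}\,oxoETE
\end{aligned}$$

Everything else — phospholipid (PL), Ca²⁺, the GSH/GSSG and NADPH/NADP⁺
couples, a generic lipid peroxide pool (LOOH) standing for the cell's
oxidative stress, and the enzyme totals — is a fixed *environment*
(`los_environment()`), exactly the quantities an experiment poises.

## The 5-LO catalytic cycle

The centrepiece is the reduced 5-LO cycle. The enzyme's many microstates
collapse under the QSSA into three pools whose weights are algebraic terms
(`five_lo_terms()`):

* the **ferric (active) pool**, weight `delta_L`, partitioned over the
  catalytic site (free, AA, HT, or the competitive inhibitor PF) and a
  regulatory AA site (`delta_HP = 1 + AA/K_AA_i`) whose occupation forms a
  dead-end complex — this is the substrate inhibition that makes the AA
  dependence of the oxygenase rate non-monotonic (peak near 77 µM with the
  default constants);
* the **enzyme–HP complex**, weight `Delta_HP`, fed by the oxygenase step
  and by weak rebinding of free HP (`k_3 K_d3`), drained by HP release
  (`k_3`) and the slow LTA4-synthase step (`k_LTAsyn`). Because rebinding
  is weak (`K_d3 = 1.3e-4`), endogenously generated HP — still enzyme-bound
  — is the preferred LTA4-synthase substrate, while exogenous HP
  contributes only marginally;
* the **ferrous (inactive) pool**, weight `Delta_redox`: the balance of
  everything that reduces the catalytic iron (a slow spontaneous path, the
  reduced lipid products HT and LOH, and the redox inhibitor Z, rate
  `rho7 Z/K_dz`) against everything that re-oxidizes it (the spontaneous
  path scaled by the small equilibrium factor `K_r`, plus the peroxides
  `rho1 (LOOH + HP)`). At zero peroxide the resting enzyme is almost
  entirely ferrous; peroxide and Ca²⁺ (through `k_ox2`) switch it on. This
  single term carries the model's pharmacology: a redox inhibitor loses
  potency exactly in proportion to the available peroxide, and the HP it
  forces through the pseudo-peroxidase reappears as HT and 5-oxoETE.

Three exact identities tie the fluxes together and are asserted in the test
suite: the pseudo-peroxidase pairs (`V_HTsyn = V_HPcons`,
`V_LOHsyn = V_LOOHcons`), and the carbon balance
`V_AAcons = V_LTAsyn + V_HPsyn`, which is what makes AA + HP + LTA4
conserved when sources, sinks and the HP/HT interconversion are switched
off.

## Reconstruction choices

The published equation set for this pathway survives only in a typeset form
whose operator grouping does not flatten unambiguously, and its constants
table prints two values under one Ca²⁺-constant symbol and none for four
GPx quantities. The package therefore fixes the algebra by re-deriving the
reduced cycle and resolving each ambiguity against the model's own
documented behaviors. The load-bearing choices, each revisitable through
`los_parameters()` overrides:

* **Ca²⁺ site assignment.** The mM-scale printed value (7.11 mM) is
  assigned to `K_2Ca` (the site entering `rho1`, `rho2`, `rho7` and
  `Delta_2Ca`), the µM-scale value (14.4 µM) to `K_3Ca` (the Z-state
  occupancy factor `Delta_zCa`). With the alternative assignment the
  half-activation of HP production by Ca²⁺ lands near 5 µM instead of the
  documented 2–3 µM, and the baseline redox balance is pushed ~60-fold
  toward the ferrous state, destroying the competitive inhibitor's
  potency scale.
* **`rho7`'s Ca modulation uses `K_2Ca`, not `K_3Ca`.** If the
  inhibitor-mediated reduction rate and the Z-state occupancy shared one
  constant, their Ca factors would cancel exactly in the redox-inhibitor
  term of `Delta_redox`, and at millimolar Ca the redox inhibitor would be
  ~60-fold more potent than every reported potency for its class.
* **HEDH denominator grouping.** The occupancy factors multiply only the
  adjacent rate term. The fully distributed alternative multiplies the
  NADP⁺ term by (1 + NADPH/K), throttling HEDH roughly 700-fold at the
  scenario's 2 mM NADPH; HT then accumulates far past its 0.54 µM
  inhibition constant at any realistic flux and every potency leaves its
  reported range by an order of magnitude.
* **Pseudo-peroxidase bracket.** The fluxes are
  `rho1 (Fa/Delta_tot)(HP·Delta_redox − HT/K_ox)` and the LOOH analogue:
  the reverse (product-driven) reduction of ferric enzyme is independent
  of the peroxide concentration. Multiplying the whole bracket by HP
  instead creates an HP↔HT shuttle whose positive feedback collapses the
  system at nanomolar redox-inhibitor doses.
* **cPLA2 activity fraction.** The printed maximal cPLA2 rate
  (450 µM/min) exceeds the maximal throughput of everything downstream
  (≈31 µM/min through the 5-LO cycle, ≈8 µM/min through HEDH) by more
  than an order of magnitude; taken literally, AA grows without bound and
  no inhibitor can reduce total product flux at steady state. The
  environment therefore carries `cpla2_scale` (default 1); the packaged
  cellular scenarios use the calibrated value 1.86e-3, i.e. an effective
  AA supply of ~0.8 µM/min, under which true steady states exist and the
  competitive inhibitor's potency sits at its binding constant, as
  reported.

## The calibrated GPx block

Four constants were never published: the GPx total and its HP, GSH and HT
constants. `calibrate_gpx()` tunes {`GPx_full`, `Km_HP_GPx`, `K_HT_GPx`,
`cpla2_scale`} by Hooke–Jeeves against the zero-oxidative-stress potency
baseline (`baseline_potency_targets()`): redox inhibitor ≈ 0.98/0.96 µM
against LTA4/5-oxoETE, competitive inhibitor ≈ 0.122/0.125 µM. The tuned
values (`GPx_full = 6490` activity units, `Km_HP_GPx = 23.3` µM,
`K_HT_GPx = 50` µM, `Km_GSH_GPx = 50` µM held at its literature-range
default) ship as package defaults, flagged in
`attr(los_parameters(), "calibrated")`. The achieved baseline is
868/890 nM (redox) and 126/191 nM (competitive); the competitive
inhibitor's 5-oxoETE potency runs ~50% above its LTA4 potency because LTA4
synthesis retains a share of HP-rebinding sensitivity that total flux does
not — a structural property of this reconstruction, not a tuning residue.

## The dose–response protocol

`inhibition_percent()`, `dose_response()`, `find_icxx()` and
`potency_grid()` implement: run the uninhibited system to a full steady
state (all five species dynamic), then add the inhibitor and compute the
new steady state of HP, HT, LTA4 and 5-oxoETE with **AA held at its poised
baseline level**. The clamp reflects that the cellular AA level is a
property of the stimulus (PL and cPLA2), not of the 5-LO branch; without
it, mass action lets AA rise until 5-LO throughput is fully restored and
no inhibitor could ever reduce total product flux — every potency in the
reported range presupposes the poised-AA reading. Percent inhibition is
`100(1 − X_st(dose)/X_st(0))`, reported as computed: negative values
(disinhibition) are the model's key prediction for redox inhibitors under
oxidative stress, where the peroxide-fed pseudo-peroxidase converts the
blocked LTA4 flux into HT and 5-oxoETE.

IC50/IC80 extraction uses a 13-point log-spaced pre-scan over 1 nM–1 mM
and log-dose bisection to |Inh% − level| ≤ 0.1; non-monotone curves return
the lowest crossing, flagged.

## What reproduces, and what does not

With the packaged constants the model reproduces: the substrate-inhibition
peak of the oxygenase rate (interior maximum near 77 µM AA); Ca²⁺
half-activation of HP production well below 3 µM; the zero-stress potency
baseline within ~20% (the competitive 5-oxoETE cell excepted, +53%); the
strict loss of redox-inhibitor potency against 5-oxoETE with rising
peroxide; the peroxide-insensitivity of the competitive inhibitor; the
control-stress competitive IC80 (429 vs 518 nM); and the signature of
Figure-style peroxide-consumption experiments (only the redox inhibitor
consumes an exogenous 10 µM peroxide pool).

Known quantitative departures, left visible rather than tuned away:

* the redox inhibitor's peroxide antagonism is stronger than reported —
  its LTA4 IC50 grows roughly as (LOOH + HP)/HP, reaching ~7.9 µM at
  LOOH = 100 µM against a reported 1.45 µM; the reported *decrease* of its
  IC50 from 0 to 5 µM peroxide (980 → 860 nM) has the opposite sign of
  anything this Delta_redox structure can produce;
* the competitive inhibitor's potency is fully peroxide-flat here, whereas
  the reported values drift ~2.3-fold over the peroxide grid;
* the glutathione threshold between phospholipid supplies of 117 and 125
  µM is not resolved: both are fully suppressed by a reduced glutathione
  pool, because at the calibrated AA influx the system sits far from the
  throughput cliff that would make a 1% difference in supply decisive;
* the non-redox inhibitor's trajectory in the peroxide-consumption setting
  tracks the uninhibited one to ~4%, not 1%, since baseline HP production
  is 5-LO-dependent.

## Numerics and problem sizes

Integration is `deSolve::lsoda` (relative tolerance 1e-8 for time courses,
1e-9 inside the steady-state relaxation; absolute 1e-10/1e-11). Steady
states relax over doubling time windows (up to ~1e6 min) and are polished
by damped Newton iteration with a finite-difference Jacobian
(`pracma::jacobian`) to a residual of 1e-12–1e-9 µM/min, with per-species
convergence reporting — a fully inhibited system has no AA steady state
while its products still settle, and says so. Negative concentration
excursions beyond −1e-9 µM are warned about, never clamped. The potency
grid (4 peroxide levels × 2 inhibitors × 2 outputs, IC50 + IC80) is ~50
steady-state solves per cell and runs in ~6 minutes; test-suite problem
sizes (20-point AA sweeps, 5 recovery seeds, 121-point Ca grids) were
chosen so the whole suite completes in well under half an hour.

## Synthetic data and the fitting layer

`generate_synthetic_dataset()` evaluates any observable — a species, a
flux, or a sum like `"HP+HT"` — over a design of states, time points or
steady states, and adds i.i.d. Gaussian noise under a recorded seed;
`noise_sd = 0` returns exact model values, so the least-squares objective
(`los_objective()`, unit weights by default) is zero at the generating
parameters. The from-scratch Hooke–Jeeves pattern search (`hooke_jeeves()`)
searches log10-transformed coordinates for constants spanning decades.
`recover_parameters()` closes the loop: small parameter subsets are
refitted from perturbed starts, with a flat-profile probe that flags
parameters the design cannot see.

The generator emulates measurement noise on otherwise exact kinetics. It
does not emulate enzyme self-inactivation (deliberately absent from the
rate laws, which treat the active 5-LO total as a constant), systematic
assay biases, or inter-preparation variability — so successful recovery
here demonstrates the identifiability machinery, not robustness to the
full error structure of bench data.

## Worked example

```{r example, eval = FALSE}
p <- los_parameters()
e <- los_scenario("fig10_table2_base", LOOH = 5)  # control stress
ss <- los_steady_state(e, p)
ss$state
ic50 <- find_icxx(50, "PF", "LTA4", e, p)
attr(ic50, "nM")
```

The full potency surface is one call,
`potency_grid(c(0, 5, 10, 100), levels = c(50, 80))`, and the shell
interface (`inst/cli/losmodel.R`) exposes the same computations as
`simulate`, `steady`, `dose-response`, `table2`, `export-sbml`,
`calibrate-gpx` and `fit-demo` subcommands. `export_sbml()` writes the
whole model as SBML Level 3 with MathML kinetic laws generated from the
same expressions the solver evaluates; `sbml_rhs()` re-evaluates the
serialized document and is tested to agree with the native right-hand side
to 1e-6.
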