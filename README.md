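# losmodel

A mechanistic kinetic model of leukotriene A4 (LTA4) and 5-oxoETE
synthesis in leukocytes — the "LOS" pathway — for researchers studying
5-lipoxygenase (5-LO) pharmacology: how the enzyme's redox cycle couples
cellular oxidative stress to the efficacy of the two major inhibitor
classes (redox inhibitors such as zileuton, and non-redox competitive
inhibitors).

## The model

Five dynamic species (µM): arachidonic acid (AA), 5-HPETE (HP), 5-HETE
(HT), LTA4 and 5-oxoETE, with

```
dAA/dt     = V_PLA2 − V_AAcons
dHP/dt     = V_HPsyn − V_HPcons(pp) − V_GPx
dHT/dt     = V_HPcons(pp) + V_GPx − V_HEDH − k_HTd·HT
dLTA4/dt   = V_LTAsyn − k_LTAd·LTA4
doxoETE/dt = V_HEDH − k_oxoETEd·oxoETE
```

The 5-LO fluxes come from a quasi-steady-state reduction of the enzyme's
catalytic cycle into three pools — ferric (active), the enzyme·HP complex,
and ferrous (inactive) — with substrate inhibition through a regulatory AA
site, competitive inhibition by HT and by the non-redox inhibitor (PF,
binding constant K_PF = 126 nM), and a redox balance `Delta_redox` in
which lipid peroxides (HP and a fixed pool LOOH representing oxidative
stress) re-oxidize the iron while the redox inhibitor Z reduces it.
cPLA2 (Ca²⁺-activated AA supply), glutathione peroxidase (ping-pong, GSSG
product-inhibited) and 5-hydroxyeicosanoid dehydrogenase (reversible
bi-bi ping-pong with NADP⁺) close the pathway. All published kinetic
constants are packaged; the four unpublished GPx quantities carry
documented calibrated defaults (`attr(los_parameters(), "calibrated")`,
see the vignette).

The central pharmacological result the model expresses: a competitive
inhibitor suppresses LTA4 and 5-oxoETE equally at any oxidative-stress
level, while a redox inhibitor loses potency in proportion to the
peroxide pool and re-routes flux into HT/5-oxoETE — under high stress it
can *increase* 5-oxoETE while still suppressing LTA4.

## Worked example

```r
library(losmodel)
p <- los_parameters()
e <- los_scenario("fig10_table2_base", LOOH = 5)  # control oxidative stress
los_steady_state(e, p)
#> LOS steady state (ode-relaxation+newton)
#>          AA          HP          HT        LTA4      oxoETE
#> 1.72968e-02 1.42541e+02 1.56972e-01 2.33846e-05 1.11557e+02
#> residual max|dX/dt| = 1.11e-16 uM/min; converged: TRUE

attr(find_icxx(50, "PF", "LTA4", e, p), "nM")
#> [1] 126.3
attr(find_icxx(50, "Z", "LTA4", e, p), "nM")
#> [1] 1778.3
```

The steady state shows the poised cell: AA is held low (~17 nM) by the
active enzyme, HP carries the redox signal (~140 µM at control stress with
the calibrated GPx), and the degradation sinks set LTA4 and 5-oxoETE. The
two IC50s show the potency gap between the inhibitor classes at control
stress (competitive ≈ its 126 nM binding constant; redox ≈ 1.8 µM).
`potency_grid(c(0, 5, 10, 100), levels = c(50, 80))` computes the full
potency surface across oxidative-stress levels; `dose_response()` returns
individual curves; `export_sbml()` serializes the model as SBML Level 3.
A shell interface is included (`inst/cli/losmodel.R`) with `simulate`,
`steady`, `dose-response`, `table2`, `export-sbml`, `calibrate-gpx` and
`fit-demo` subcommands.

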