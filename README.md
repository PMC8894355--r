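# nashmet

Nash-equilibrium simulation of liver energy metabolism in R.

`nashmet` is for researchers in organ preservation and metabolic systems
biology who want to simulate how a stored organ's energy state evolves —
ATP content, adenylate energy charge, lactate, ammonia, urea, pH —
without measuring a single rate constant.  The package treats a
metabolic network as a game: every pathway node *j* repeatedly minimizes
its own dimensionless Gibbs free energy

    min  G_j/RT = Σ_i n_ij [ ΔG⁰_f,i(T)/RT + ln x_ij ]
    s.t. n_j = n_j⁰ + S_j ξ_j ≥ 0

over its reaction extents ξ_j (which makes every elemental mass balance
hold by construction), while inter-pathway transport fluxes couple the
nodes.  The network solution is the fixed point at which no node can
improve given the others' fluxes — a Nash equilibrium, converged by
successive substitution on the transport fluxes.  Temperature enters
through a Gibbs–Helmholtz correction of the tabulated formation
energies, so the same model runs static cold storage (4 °C, University
of Wisconsin solution flush) and warm ischemia (37 °C) with no extra
parameters.

The package ships:

* a curated species thermodynamics table (formation energies,
  enthalpies, standard deviations) and an 11-node rat-liver
  superstructure — glycogen metabolism, glycolysis, pyruvate
  fermentation, glutaminolysis, TCA cycle, oxidative phosphorylation,
  urea cycle, glutathione metabolism, serine–glycine interconversion,
  citrate shuttle and fatty-acid synthesis — with every reaction
  balanced in all elements and charge;
* a primal active-set Newton solver for the per-node constrained Gibbs
  minimization, with an exhaustive grid-search oracle for testing;
* scenario runners (`run_scs()`, `run_wi()`), derived observables, and
  Monte-Carlo propagation of the formation-energy uncertainties with
  generalized-gamma distribution fitting;
* deterministic toy fixtures with closed-form ground truth, and a thin
  command-line driver (`inst/cli/nashmet.R`).

## Worked example

```r
library(nashmet)

db    <- liver_thermo()
model <- build_liver_model(db = db)
scs   <- run_scs(model, db)      # 4 C + UW flush, 1 day per iteration

tail(as.data.frame(scs)[c("time", "atp_mM", "energy_charge",
                          "lactate_mM", "ammonia_mM", "urea_mM", "ph")], 1)
#>    time   atp_mM energy_charge lactate_mM ammonia_mM  urea_mM       ph
#> 60   60 4.565590     0.6343769   4.327884   2.306610 1.724395 7.408073

attr(scs, "convergence")
#> <convergence_log> converged in 60 outer iterations (tol 0.001)
#> (2-norm of the transport-flux change per iteration, mM scale:
#>  6.199, 3.957, 2.608, 0.524, ... , 0.000987)
```

Reading the output: starting from a node-wise chemical equilibrium
(ATP 7.57 mM, energy charge 0.75, lactate 2.93 mM), the flushed,
hypoxic liver loses ATP and energy charge monotonically while lactate,
ammonia and urea accumulate, and the outer loop's transport-flux norm
decays below the 1e-3 tolerance.  Rerunning at 37 °C with `run_wi()`
depletes ATP roughly three times faster at matched iteration counts —
the warm-ischemia phenotype — because glycogenolysis and glutamine
hydrolysis strengthen with temperature under the Gibbs–Helmholtz
correction.

```r
mc <- run_uncertainty(model, db, n = 20, seed = 1)
subset(as.data.frame(mc$table), quantity %in% c("atp_mM", "energy_charge"),
       select = c(quantity, average, variance, percent_variance))
#>        quantity   average     variance percent_variance
#> 1        atp_mM 4.5730243 2.491861e-03       0.05449113
#> 13 energy_charge 0.6340042 2.620987e-04       0.04134001
```

See `vignettes/liver-energy-metabolism.Rmd` for the model's
assumptions, the calibration choices, and the known deviations of the
packaged desk-scale model.

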