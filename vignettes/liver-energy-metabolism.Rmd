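---
title: "Nash-equilibrium simulation of liver energy metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nash-equilibrium simulation of liver energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nashmet)
```

## The model

`nashmet` simulates a metabolic network as a collection of competing
pathway players.  Each pathway node $j$ (glycolysis, the TCA cycle, the
urea cycle, ...) repeatedly solves its own nonlinear program

$$\min_{\xi_j}\; \frac{G_j}{RT}
  = \sum_{i=1}^{C_j} n_{ij}\left[\frac{\Delta G^0_{f,i}(T)}{RT}
  + \ln x_{ij}\right],
  \qquad n_j = n_j^0 + S_j\,\xi_j \ge 0,$$

where $S_j$ is the node's stoichiometric matrix, $\xi_j$ the vector of
reaction extents, $n_{ij}$ species amounts (pmol/cell) and
$x_{ij} = n_{ij}/\sum_i n_{ij}$ mole fractions.  Parameterizing in
extents makes every elemental mass balance hold by construction; the
only constraints left are non-negativity of amounts.  The nodes are
coupled by inter-pathway transport fluxes, and the network solution is
the fixed point at which no node can lower its Gibbs energy given the
fluxes of the others — a Nash equilibrium, converged by successive
substitution on the transport fluxes.

Two assumptions deserve emphasis:

* **Ideal solutions.**  The activity of a species is its mole fraction.
  The objective above is the standard ideal Gibbs function; no
  activity-coefficient or ionic-strength model is applied.  This choice
  is isolated in `node_gibbs()` so alternatives can be swapped in.
* **Equilibrium chemistry, not kinetics.**  Each node is driven to its
  constrained chemical equilibrium at every visit.  All "rates" in the
  simulation emerge from pool sizes, transport topology and the
  iteration structure, never from rate constants.

## Temperature

Standard formation energies are tabulated at $T_0 = 298.15$ K and
corrected to the simulation temperature with

$$\frac{\Delta G^0(T)}{RT} = \frac{\Delta G^0(T_0)}{RT_0}
  + \frac{\Delta H^0(T_0)}{R}\,\frac{T - T_0}{T\,T_0}.$$

This is the package's adopted convention (the sign of the enthalpy term
is fixed by the contract of `gibbs_helmholtz()` and its reference
values; note that the classical van't Hoff integration carries the
opposite sign).  Under this convention a reaction whose enthalpy change
has the same sign as its free-energy change is *weaker* at 4 °C than at
37 °C, which is exactly the temperature behavior the liver scenarios
rely on: cold storage slows everything, warm ischemia accelerates it.

Formation enthalpies for biochemical species are rarely tabulated.  The
packaged database constructs them as 1.1 times the formation energy
plus element-wise group increments (the increments cancel in every
balanced reaction, so each reaction enthalpy is 1.1 times its reaction
free energy).  Two species are curated individually, and these are
deliberate modeling decisions rather than data: the glucosyl unit of
glycogen (phosphorylase reaction enthalpy $-20$ kJ/mol, so
glycogenolysis accelerates with temperature) and glutamine (hydrolysis
enthalpy $-40$ kJ/mol, so ammonia release — and with it urea-cycle ATP
consumption — accelerates in warm ischemia).

## The packaged liver model

`build_liver_model()` assembles eleven pathway nodes: glutathione
metabolism (the flush entry node), glycogen metabolism, glycolysis,
pyruvate fermentation, glutaminolysis, the TCA cycle, oxidative
phosphorylation, the urea cycle, serine–glycine interconversion, the
citrate shuttle and fatty-acid synthesis (the last two gated by the
`fatty_acid_synthesis` mode; a β-oxidation node is available behind
`beta_oxidation`, off by default).  Reactions are canonical textbook
stoichiometries written in major-protonation-state species (ATP$^{4-}$,
HPO$_4^{2-}$, ...), with explicit protons and water, and every reaction
balances all elements and the charge exactly — this is asserted by the
test suite over the whole model.

Liver-specific chemistry: glucose is phosphorylated by glucokinase
(`glucose + atp -> g6p + adp + h`), glutathione synthesis
(`gly + 2 atp + glu + cys -> 2 adp + 2 pi + gsh + 2 h`) runs reversibly
— a high glutathione level from the preservation flush pushes it
backwards and regenerates ATP — serine is made from glycine via SHMT
(there is deliberately no 3-phosphoglycerate route), pyruvate ferments
to lactate, and ammonia is cleared by a complete urea cycle with
ornithine recycle and fumarate→malate→oxaloacetate regeneration of the
aspartate donor.

Three bookkeeping devices keep the chemistry well-posed:

* **Buffering.**  Every node carries the phosphate buffer pair
  (H$_2$PO$_4^-$/HPO$_4^{2-}$, p$K_a\!\approx\!7.2$) and a
  protein/imidazole-like buffer pair (p$K_a\!\approx\!7.0$, pools of
  ~33 mM) standing in for the large intracellular buffering capacity,
  plus carbonic anhydrase wherever CO$_2$/HCO$_3^-$ appear.  Without
  them, mM-scale proton fluxes would swing the free proton pool (nM
  scale) by orders of magnitude.
* **Proton standard state.**  The proton's formation-energy entry
  (+54.3 kJ/mol) is chosen so that its full chemical potential
  $g + \ln x$ vanishes near pH 7.8 — the explicit-proton bookkeeping is
  anchored at physiological pH, and tabulated pH-7 reaction affinities
  apply unchanged there.
* **Unit basis.**  Amounts are pmol/cell; concentrations use a cell
  water volume of $3.81\times10^{-14}$ L, back-computed from paired
  published statements of one ATP change in pmol/cell and in mM.  It is
  a configuration constant, not a derived quantity.

The default composition (`liver_composition()`) uses physiological
hepatocyte pools: high glycogen (200 mM glucosyl units), glutamine and
glutathione at several mM, lactate 2.8 mM, adenylates summing to
~15 mM, and — crucially — a nearly exhausted oxygen reserve
(0.35 mM across the TCA and oxidative-phosphorylation nodes)
representing the hypoxic preserved organ.  Oxygen is the single most
consequential pool: raising it recharges ATP through oxidative
phosphorylation and abolishes the energy-depletion phenotype.

## The engine

One outer iteration visits the nodes in model order.  Each visit
delivers pending incoming transports, re-minimizes the node (an inner
loop repeats the minimization until successive amounts change by less
than `inner_tol` = 1e-5 on the mM scale, which settles the
pathway-internal recycle species such as oxaloacetate and ornithine),
then offers the node's post-minimization stock of each transported
species — everything above the configured retention floor, default 0 —
on its outgoing links.  When one species leaves a node on several
links, the offer is split in proportion to the recipients'
thermodynamic demand, measured as the finite-difference drop in the
recipient's Gibbs energy per unit transferred, with an equal split as
fallback.  This update rule is the engine's central modeling choice; it
lives in one internal function and is the first thing to revisit when
adapting the package to other networks.

The outer loop terminates when the 2-norm of the change in the
transport-flux vector falls below `outer_tol` = 1e-3.  The norm is
computed on fluxes expressed in mM (through the volume basis), which
puts the packaged runs on a 10⁰–10⁻⁴ norm scale and makes the 1e-3
tolerance meaningful.  Iterations map linearly to scenario time: 1 day
per outer iteration in static cold storage, 5 minutes in warm ischemia.
This is a declared calibration, not a derivation.

## The node solver

`minimize_node()` is a primal active-set Newton method on the extent
variables.  Numerical choices:

* Problems are rescaled to unit total amount (the objective is
  homogeneous of degree one), so floors and tolerances are
  mole-fraction based.
* Amounts are floored at a mole fraction of 1e-12 inside the objective;
  species at the floor are pinned to zero as equality constraints in
  the Newton KKT system and released when their Lagrange multipliers
  change sign.  First-order optimality is measured by non-negative
  least squares over the active-bound multipliers.
* Because amounts span many orders of magnitude, the objective can be
  flat to machine precision along stiff directions while the floored
  gradient still reports a large norm.  The solver therefore accepts a
  point as converged when it is *stationary in the objective*: neither
  the Newton direction, nor a KKT-residual polish, nor an exhaustive
  single-reaction coordinate probe improves the objective beyond
  precision.  Non-convergence is always flagged, never silent.
* Solves are deterministic; there is no randomized restart.  Identical
  inputs give bit-identical trajectories.

An exhaustive grid search (`brute_force_equilibrium()`, with optional
zoom refinement) serves as the independent oracle for problems with at
most two reactions; the test suite checks solver/oracle agreement to
1e-6 on more than twenty fixture problems.

## Uncertainty propagation

`run_uncertainty()` reruns the cold-storage scenario with each
formation energy independently perturbed by $s\,(2u-1)$, $u$ uniform on
(0, 1] — the literal reading of the sampling rule, with a
truncated-normal alternative behind a flag — starting every run from
the identical initial state.  Summaries per observable: mean, variance,
percent variance ($100\,\sigma^2/\bar{x}$, the convention that
reproduces the published self-consistent table rows), type-7 quartiles
(both absolute IQR and IQR/median are reported, since the published
description is ambiguous between them), and a maximum-likelihood
generalized-gamma fit that falls back to the ordinary gamma when the
extra shape parameter is not supported (likelihood-ratio threshold
3.84).

A known, deliberate divergence: with perturbations of realistic
magnitude (kJ/mol-scale standard deviations), equilibrium-poised trace
pools — AMP through adenylate kinase, ammonia through glutaminase —
respond exponentially and show percent variances at the 0.1–50 %
level.  Only pool- or stoichiometry-pinned quantities (ATP content,
energy charge, lactate) reach the sub-0.1 % regime reported for the
original model.  The corresponding acceptance check is intentionally
left failing rather than weakened; the reproducibility of the
Monte-Carlo pipeline under a fixed seed is exact (byte-identical
output).

## What the fixtures do and do not show

The fixture generators (`make_isomer_pair()`,
`make_two_node_transport()`, `make_adenylate_toy()`,
`make_random_balanced()`) produce models with closed-form or
brute-force-checkable ground truth: analytic isomer splits, a scalar
fixed-point oracle for one transport link, a conserved adenylate pool
with declining energy charge, and randomly generated but exactly
element-balanced stoichiometries on a CH$_2$O monomer family (with a
deprotonated variant to exercise charge balance).  The adenylate toy is
built as a two-node supply/load pair: in this engine a single node with
no transports equilibrates in one outer iteration, so multi-iteration
energy-charge dynamics require at least one transport link.

Passing these tests establishes that the solver finds constrained
Gibbs minima, that conservation is exact, and that the engine's fixed
point matches independent iteration — on ideal-solution, desk-scale
networks.  They do not validate kinetic realism, membrane transport
energetics, osmotic/volume effects, or the completeness of the liver
reaction set, none of which the model represents.

## Known limitations

* The liver model is a faithful-by-pathway reconstruction: the pathway
  set and the liver-specific chemistry are fixed, but the exact
  reaction list behind the original superstructure is not public, so
  trajectory *magnitudes* (e.g. final ATP of ~4.6 mM rather than
  0.63 mM) are not expected to reproduce published values; trends are.
* The packaged cold-storage run shows a mild pH decline
  (7.59 → 7.41), where the original reports a rise (7.76 → 8.35).  In
  this model the urea-cycle proton release outweighs the proton
  consumption of fermentation and the oxygen-starved electron transport
  chain; raising the oxygen reserve flips the pH trend but also
  recharges ATP, contradicting the primary energy-depletion phenotype,
  so the hypoxic reserve is kept.
* Problem sizes used by the test suite — twenty-plus oracle fixtures,
  ten temperatures, full cold-storage and warm-ischemia runs of the
  eleven-node model, and a twenty-run Monte-Carlo — are the package's
  chosen desk-scale study conditions.

## A worked run

```{r, eval = FALSE}
db <- liver_thermo()
model <- build_liver_model(db = db)

scs <- run_scs(model, db)     # 4 C, University of Wisconsin flush
wi  <- run_wi(model, db)      # 37 C, no flush

attr(scs, "convergence")      # decaying transport-flux norms
plot(scs)                     # adenylates, energy charge, metabolites, pH

mc <- run_uncertainty(model, db, n = 20, seed = 1)
mc$table                      # averages, variances, percent variances
```
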