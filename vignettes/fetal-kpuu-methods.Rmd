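---
title: "Predicting fetal exposure to placental P-gp substrates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fetal exposure to placental P-gp substrates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalkp)
```

## The problem

Most drugs taken during pregnancy cross the placenta. For a drug that moves
only by passive diffusion, fetal and maternal unbound plasma exposures
equilibrate and the fetal-to-maternal unbound AUC ratio,

$$K_{p,uu} = \frac{f_{u,f}\,\mathrm{AUC}_{fetal}}{f_{u,m}\,\mathrm{AUC}_{maternal}},$$

is 1. Placental efflux transporters — above all P-glycoprotein (P-gp),
expressed on the apical (maternal-facing) membrane of the
syncytiotrophoblast — pump drug back toward the maternal circulation and
push $K_{p,uu}$ below 1. Because umbilical-vein (UV) sampling is only
possible at delivery, $K_{p,uu}$ at earlier gestational ages cannot be
measured; it has to be predicted. This package implements a complete
in-vitro-to-in-vivo workflow for that prediction and the simulation
machinery used to verify it against term cord-blood data.

## From Transwell plates to an efflux ratio

A polarized monolayer of P-gp-overexpressing MDCK cells on a Transwell
insert mimics the syncytiotrophoblast: the apical chamber plays the maternal
side, the basal chamber the fetal side. Each directional run measures drug
accumulation in the receiver chamber over time. The apparent permeability is

$$P_{app} = \frac{cA(R)}{\mathrm{AUC}_D \cdot A},$$

the final cumulative receiver amount over the donor concentration-time
integral and the insert area, and the efflux ratio is
$ER = P_{app}(B{\to}A) / P_{app}(A{\to}B)$. Two corrections matter and both
are implemented in `cumulative_receiver_amount()` and `donor_auc()`:

* **Sampled-volume correction.** Receiver draws (100 µl here) are replaced
  with blank buffer, so each measured concentration reflects only the mass
  still in the chamber. The cumulative amount at sample $k$ adds back every
  previously withdrawn aliquot:
  $cA_k = V_R C_k + \sum_{j<k} v_j C_j$.
* **Donor-AUC denominator.** Using the trapezoidal donor AUC instead of
  $C_0 \cdot t$ corrects for depletion of the donor during the experiment.

Experiments are QC-gated (`qc_gate()`): Lucifer yellow
$P_{app} < 2\times10^{-6}$ cm/s certifies tight junctions, and the
positive-control substrate (quinidine for P-gp, prazosin for BCRP) must show
$ER > 7$. The transporter-mediated efflux ratio is the inhibitor-sensitive
difference $ER_{P\text{-}gp} = ER_{TRQ(-)} - ER_{TRQ(+)}$, with tariquidar
as the P-gp inhibitor.

Design choices where the protocol leaves room:

* $P_{app}$ is computed from the final cumulative amount over the
  full-window donor AUC (the cumulative form above); a slope-regression
  variant is available via `papp_from_experiment(method = "slope")` as a
  linearity diagnostic.
* Triplicate wells are averaged at the concentration level inside one
  experiment (`load_plate_csv()`); experiment-level replicates are never
  pooled before ER computation, because the prediction propagates
  experiment-to-experiment variability.
* Donor draws (10 µl of 500–1000 µl) shrink the donor volume; the
  synthetic-data oracle tracks this exactly, while the estimator ignores it
  (the flux depends on donor concentration, not volume; the residual effect
  is below 2%).
* The insert area defaults to 1.12 cm² (standard 12-well insert) and is
  configurable.
* Assay bookkeeping is done in minutes and µM; conversion to cm/s happens
  once, at the `apparent_permeability()` boundary.

## REF scaling and the $K_{p,uu}$ prediction

With negligible fetal elimination, the steady-state balance of clearances
into and out of the fetal compartment relates $K_{p,uu}$ to the ratio of
active efflux to passive diffusion clearance, and the in vitro efflux ratio
measures exactly that ratio — in the cell line. The relative expression
factor

$$REF = \frac{\text{P-gp abundance in placenta}}{\text{P-gp abundance in cells}}
\quad \text{(pmol per mg homogenate protein)}$$

rescales transporter activity to tissue, giving the central prediction
equation implemented in `predict_kpuu()`:

$$K_{p,uu} = \frac{1}{1 + REF \cdot ER_{P\text{-}gp}}.$$

A non-substrate ($ER_{P\text{-}gp}=0$) maps to exactly 1; the fraction
transported by P-gp is $f_t = 1 - K_{p,uu}$.

`summarize_prediction()` pairs each experiment's $ER_{P\text{-}gp}$ with the
in vitro abundance measured *in that same experiment* (cell-passage
abundance drift is real and measured), averages the per-experiment
$K_{p,uu}$ values into the point estimate, and reports the alternative
estimator ($K_{p,uu}$ of the mean ER and mean REF) as well — for strong
substrates the two differ, and the reference data are ambiguous about which
averaging path produced one of the published drug-level means, so both are
exposed rather than guessing.

**Uncertainty.** The reference analysis reports a pooled-variance 90%
interval without specifying the propagation mechanism. Here it is a seeded
Monte-Carlo (`kpuu_ci_montecarlo()`): $ER_{P\text{-}gp}$ and the two
abundances are drawn from independent normals truncated at zero (ER) or at
a small positive floor (abundances), and the 5th/95th percentiles of the
implied $K_{p,uu}$ are reported. This choice is reproducible, makes its
independence assumptions explicit, and degenerates to the point estimate at
zero variance. Default $10^5$ draws; the truncation floor ($10^{-6}$
pmol/mg) only matters for abundance CVs far larger than any measured here.

Full precision is carried everywhere internally; rounding to the reported
two decimals happens only at the reporting boundary.

## The compact maternal-fetal PBPK model

The simulator (`simulate_mf_pbpk()`) deliberately resolves only what the
placental question needs: a gut depot (first-order `ka` after lag `tlag`,
bioavailability applied at absorption), one lumped maternal central
compartment with systemic clearance `cl_maternal * induction_scalar`, a
placental tissue compartment, and one fetal compartment. Everything upstream
of the placenta (organ-resolved maternal disposition, CYP3A
induction/inhibition mechanics, ritonavir interaction) is consumed as
configuration through `cl_maternal`, `f_oral` and `induction_scalar`;
$K_{p,uu}$, UV/MP shape, fitting and gestational-age scaling all live in the
placental-fetal unit.

Unbound concentrations drive all placental exchange. The maternal-placental
and placental-fetal passive clearances are the same intrinsic bidirectional
diffusion clearance `cl_int_pd_placenta`, each capped by its adjacent blood
flow (`effective_pd_clearance()`: transfer cannot exceed perfusion). The
active efflux clearance `cl_pm` moves drug from placental tissue to maternal
plasma, acting on the unbound placental concentration; active
maternal-to-placenta and fetal-to-placenta transport are fixed at zero
(apical-efflux-only topology). Fetal elimination defaults to zero —
CYP3A7-mediated fetal hepatic clearance of these drugs is negligible.
Placental tissue binding is unreported for the drugs of interest, so
`fu_placenta` defaults to 1 and is configurable.

The passive clearance itself is anchored to midazolam
(`scale_passive_from_reference()`): the known in vivo midazolam placental
passive clearance (500 l/h) is scaled by the ratio of apparent (passive)
permeabilities measured in the same cell system.

**Closed-form steady state.** With no fetal elimination, the average net
placenta-to-fetus flux over a dosing interval vanishes at periodic steady
state, so the average unbound fetal and placental concentrations are equal,
and the placental balance gives

$$K_{p,uu} = \frac{CL_{PD,eff}}{CL_{PD,eff} + CL_{PM}},$$

with $CL_{PD,eff}$ the flow-capped maternal-side passive clearance
(`kpuu_steady_state()`). This is the derivation the simulator is tested
against (agreement within 0.5%), and it makes the structural point the whole
approach rests on: $K_{p,uu}$ depends only on the efflux-to-passive
clearance ratio, not on maternal disposition, dose or fetal volume.

**Numerics.** `deSolve::lsoda` with the analytic (constant) Jacobian,
`rtol = 1e-9`, `atol = 1e-12`, `maxsteps = 1e5`; doses are events that
deposit `f_oral * dose` into the gut depot, and all output/event times are
rounded to $10^{-6}$ h so event times sit exactly on the output grid. Mass
balance (system + eliminated vs administered) is checked on every run and
stays below $10^{-6}$ relative. On a non-finite or negative-state failure
the integrator retries once with 100-fold tighter tolerances, then raises.
Steady state is declared when the final-interval maternal and fetal AUCs are
within 2% of the previous interval; for maternal half-lives up to twice the
dosing interval this triggers within 10 doses, while at the three-interval
margin the same algebra needs about 14 doses — the default regimens use 16.

## Estimating the in vivo $K_{p,uu}$ from UV/MP data

Cord blood is drawn once per maternal-fetal dyad, at delivery — effectively
a random time within the dosing interval. `fit_clpm()` therefore fits the
*ratio* UV/MP (unbound) at each dyad's time-after-dose, not raw UV
concentrations: the ratio cancels the per-dyad maternal scale, which is
exactly why it is the preferred clinical quantity (a raw-UV objective is
available behind `fit_on = "uv"`). The objective is the absolute average
fold error,

$$\mathrm{AAFE} = 10^{\overline{|\log_{10}(pred/obs)|}},$$

minimized over $\log_{10} CL_{PM}$ in a default bracket of $[0.1, 10^5]$
l/h. A 13-point log-grid scan first verifies unimodality and brackets the
optimum, then `stats::optimize` refines it; flat objectives (insensitive
$CL_{PM}$) clear the convergence flag, ties are broken toward smaller
$CL_{PM}$ (parsimony), and dyads are unweighted (AAFE is already
log-scale). `compare_hypotheses()` reports the fitted-efflux vs passive-only
AAFE contrast that carries the evidence for active efflux.

## Gestational-age scaling

Two biological quantities move placental transfer across gestation, and they
scale different clearances (`scale_clpd()`, `scale_clpgp()`):

* passive diffusion tracks *placental surface area* —
  `intrinsic = term * sa_ratio`, still capped by the (smaller) GA blood
  flow;
* active efflux tracks *total placental P-gp abundance* —
  `cl_pm_ga = term * abundance_ratio`. Abundance per gram rises toward
  early gestation, but the smaller placenta wins: total abundance at GW20 is
  about 40% below term.

The default physiology table (`default_ga_table()`) carries two anchor rows:
term (flows 45 l/h, ratios 1) and GW20 (flow 27.5 l/h, abundance ratio
0.60, surface-area ratio 0.39 — the last back-calculated from published
term/GW20 passive-clearance pairs rather than printed directly, and marked
as derived). Intermediate ages interpolate linearly; outside 20–40 weeks
the edge row is used with an extrapolation warning, since fetal physiology
is not reliably tabulated before GW20 and maternal-placental circulation is
not established before GW13. Which flow caps which exchange is not settled
in the literature; the default caps each exchange by its own adjacent flow.

A consequence worth stating: because $K_{p,uu}$ depends only on the
efflux-to-passive ratio, its direction of change with gestational age
depends on whether the passive clearance is perfusion-capped. For a
permeability-limited drug, passive falls faster (surface area) than efflux
(abundance) and $K_{p,uu}$ drops at GW20; for a flow-capped drug the
*effective* passive clearance falls only as far as the flow does, and the
ratio can move either way. The lumped model also leaves maternal exposure
GA-invariant by construction — maternal parameters at another GA are a
user input, not a model output.

## What the synthetic data emulate — and what they do not

`simulate_transwell_pair()` integrates the two-chamber mass balance
$V_R\,dC_R/dt = A\,(P_{D\to R} C_D - P_{R\to D} C_R)$ exactly (matrix
exponential between events) with every sampling event handled discretely:
receiver draws replaced by blank buffer, donor draws shrinking the donor
volume. Measurement error is multiplicative log-normal (concentrations are
positive and LC-MS/MS error is scale-proportional), mean-one, default CV 5%.
Emulated protocol conditions: 2 µM donor, 12-well geometry (0.5/1 ml),
100 µl receiver draws at 15/30/45/60 min, 10 µl donor draws at start and
end.

Two-compartment physics makes the back-flux coefficient in the A→B
direction equal to the *large* B→A permeability, so high-ER settings leave
sink conditions unless absolute permeabilities are small: the recovery
studies use `papp_a2b = min(1e-7, 5e-6/ratio)` cm/s so that
$P_{B\to A} A T / V_R \ll 1$ in both directions. Two things follow for
interpreting tests. First, recovery of programmed ratios within 2%
demonstrates estimator correctness under sink conditions, not robustness to
sink violation — a real three-compartment monolayer has *less* A→B
back-flux than this oracle, because the basolateral membrane, not the
pump, limits re-entry. Second, in this oracle the $C_0$-denominator's
depletion error partially cancels the shared back-flux loss at the ER
level, so the donor-AUC advantage is asserted where it is unambiguous: on
the $P_{app}$ of the depleting-donor direction.

`simulate_clinical()` emulates sparse dyad sampling: each dyad gets
log-normally perturbed maternal parameters (`v_maternal`, `cl_maternal`,
`ka`; default CV 30%), one sampling time uniform on [1 h, interval] after
the final dose, and independent log-normal residual error (default CV 20%)
on UV and MP. It does not emulate: delivery-induced physiology, placental
metabolism, non-steady-state dosing histories, or correlated UV/MP assay
error. The parameter-recovery study in the test suite uses 12 dyads, 20%
residual CV and 50 seeds per truth ($K_{p,uu} \in \{0.1, 0.16, 0.5\}$) —
at that noise level the sampling SD of the fitted $\log K_{p,uu}$ is about
8%, so individual seeds can land outside ±20% by chance; the suite asserts
median bias below 5% and at least 80% of seeds within ±20%.

## Worked example

```{r}
tab <- pgp_reference_experiments()
dex <- tab[tab$drug == "DEX", ]
pred <- summarize_prediction(
  data.frame(er_pgp = dex$er_no_inhibitor - dex$er_inhibitor,
             invitro_abundance = dex$invitro_abundance_pmol_mg),
  in_vivo = attr(tab, "invivo_mean"), in_vivo_sd = attr(tab, "invivo_sd"),
  seed = 17)
pred
```

```{r}
ex <- example_params("drv_gw38")
p <- ex$params
p$cl_pm <- er_from_kpuu(0.16, 1) * effective_pd_clearance(
  p$cl_int_pd_placenta, p$q_placenta_maternal) # efflux for Kp,uu = 0.16
sim <- simulate_mf_pbpk(p, ex$regimen)
kpuu_from_simulation(sim)$kpuu
kpuu_steady_state(p)
```

## Known limitations

* Single-transporter scaling only; joint P-gp + BCRP efflux is out of
  scope (the ER inputs may come from either cell line, one at a time).
* The mapping between an intrinsic efflux clearance fitted in a richer,
  membrane-resolved placental model and this lumped model's `cl_pm` is
  model-specific; literature clearance values fitted elsewhere should be
  treated as non-transferable, while $K_{p,uu}$ itself transfers.
* Maternal disposition is consumed, not predicted: no mechanistic enzyme
  kinetics, no drug-drug interaction prediction, no protein-binding
  prediction.
* Saturable (Michaelis-Menten) efflux is not modeled; the assay protocol is
  single-concentration and the in vivo model is linear, which the
  dose-superposition test exploits.
```
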