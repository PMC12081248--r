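---
title: "Methods: whole-body PBPK simulation of transplant-phase drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK simulation of transplant-phase drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pbpkddi` simulates the pharmacokinetics of the drugs given around
hematopoietic stem-cell transplantation — conditioning agents, anticonvulsant
prophylaxis, azole antifungals, antivirals, antiemetics and the
calcineurin/mTOR immunosuppressants — and the interactions among them, so
that dosing regimens can be stress-tested against therapeutic windows before
a patient ever receives them. This vignette is the package's own account of
the model: the equations it integrates, the assumptions behind them, the
parameters that matter, and the limits of what its tests demonstrate.

## The whole-body model

Each drug is tracked as molar amounts in fourteen compartments: lung, liver,
gut, kidney, muscle, adipose, skin, brain, heart, bone, spleen, a lumped
"rest" tissue, and arterial and venous blood. Blood flows from the venous
pool through the lung to the arterial pool and back through the organs;
gut and spleen drain through the portal vein into the liver, so an
orally absorbed dose meets gut-wall and hepatic enzymes in series before
reaching the systemic circulation (first pass). All tissues are
perfusion-limited: the venous outflow of organ $T$ carries blood
concentration $B \cdot C_T / K_{p,T}$, where $B$ is the blood:plasma ratio
and $K_{p,T}$ the tissue:plasma partition coefficient,

$$V_T \frac{dC_T}{dt} = Q_T \left( C_{art} - \frac{B\,C_T}{K_{p,T}} \right) - \text{elimination}_T .$$

Partition coefficients are computed from lipophilicity, plasma protein
binding and a shipped tissue-composition table (neutral lipid, phospholipid,
water; phospholipid treated as 30% lipid-like) with tissue binding
approximated from plasma binding. One method, applied uniformly. Ionisation
is not modelled; where the octanol-water logP visibly overstates tissue
partitioning (strongly ionised acids such as phenytoin, or extreme
lipophiles such as itraconazole) the compound file carries an *effective*
partitioning lipophilicity calibrated to the observed distribution volume,
and says so in a comment. This is ordinary middle-out practice: structural
parameters from physiology, a small number of drug parameters refined
against observed behaviour.

Reference physiology describes a 73 kg adult male (cardiac output 360 L/h,
hepatic blood flow 91.8 L/h split between hepatic artery and portal vein).
Organ volumes scale linearly with body weight; cardiac output and all
regional flows scale with weight^0.75, so a 25 kg child perfuses each
kilogram of tissue faster than an adult — the physiological basis for the
faster weight-normalised clearance of busulfan in children, reinforced by a
piecewise-linear ontogeny factor on glutathione-S-transferase A1 (1.4 at
birth declining to 1.0 by age 12). Flow conservation (venous return equals
cardiac output) is enforced by construction and re-validated on every
individual, sampled or not.

### Absorption and formulations

Oral doses enter a gut-lumen state and are absorbed into gut tissue with a
first-order rate constant. Solid formulations with dissolution-limited
uptake use a Weibull release profile $W(t) = 1 - e^{-(t/\tau)^\beta}$,
implemented as an analytic forcing flux (the superposition of
$F \cdot D \cdot W'(t - t_i)$ over past doses) rather than extra solid
states; the unreleased remainder is therefore known in closed form and
enters the mass-balance audit exactly. Formulation labels on dose events
select named absorption variants from the compound file, and a fed-state
flag applies multiplicative modifiers to the dissolution time-scale and the
bioavailable fraction — the mechanism by which the posaconazole suspension
reproduces its published 2.5–3.0-fold food effect while the tablet is
food-insensitive. Intravenous boluses are state discontinuities (the
integrator restarts at every event); infusions are rectangular forcing
terms.

### Clearance

Each clearance pathway names an enzyme or transporter from a sixteen-entry
registry (CYP3A4/3A5/2C9/2C19/2D6/1A2, UGT1A1/1A3/1A4, GSTA1, P-gp, BCRP,
OATP1B1/1B3, MRP, BSEP), each with a baseline concentration $E_0$ (µmol/L
in its expressing tissue), a turnover rate $k_{deg}$, and organ weights over
which the pathway's intrinsic clearance is partitioned (CYP3A4: 90% liver,
10% gut wall; P-gp mostly gut; everything else hepatic here). Linear
kinetics scale a specific intrinsic clearance (µL/min per µmol enzyme) by
the current enzyme pool and the individual's liver volume; saturable
pathways use Michaelis–Menten kinetics on the unbound local concentration
(Km on the unbound-plasma scale). Renal clearance is drawn from the kidney
compartment at the plasma-referenced rate, i.e. a "well-stirred kidney";
for a purely hepatic drug the engine's intravenous AUC reproduces the
well-stirred closed form $CL_h = Q_h f_u CL_{int} / (Q_h + f_u CL_{int})$
to within a fraction of a percent (this is a standing test, not an input).

## Interaction mechanisms

Reversible inhibition follows the five classical forms. For one inhibitor at
unbound concentration $I$:

* competitive — $K_m \times (1 + I/K_i)$;
* uncompetitive — $V_{max}$ and $K_m$ both divided by $(1 + I/K_i)$;
* non-competitive — $V_{max}$ divided by $(1 + I/K_i)$;
* mixed — $v = V_{max} S / \left( K_m (1 + I/K_i) + S (1 + I/(\alpha K_i)) \right)$,
  with $\alpha = 1$ collapsing to non-competitive;
* irreversible (mechanism-based) inactivation — not a rate modifier at all,
  but an extra first-order hazard $k_{inact} I / (K_I + I)$ on the enzyme
  pool.

Multiple perpetrators at one target compose the way enzyme kinetics says
they must: competitive (and mixed competitive-site) terms add inside a
single denominator $1 + \sum_j I_j/K_{i,j}$, inactivation hazards add, and
induction stimuli add. The enzyme pool obeys the turnover equation

$$\frac{dE}{dt} = k_{deg} E_0 \left( 1 + \sum_j \frac{E_{max,j} I_j}{EC_{50,j} + I_j} \right) - E \left( k_{deg} + \sum_m \frac{k_{inact,m} I_m}{K_{I,m} + I_m} \right),$$

whose closed-form steady states (inactivation:
$E/E_0 = k_{deg}/(k_{deg} + k_{inact} I/(K_I+I))$; induction:
$E/E_0 = 1 + E_{max} I/(EC_{50}+I)$) are verified against the integrated
dynamics to 1%. A pool becomes a dynamic ODE state exactly when a simulated
perpetrator carries an inactivation or induction spec for it; purely
reversible interactions leave pools static. Auto-effects (a drug inhibiting
or inducing its own pathway) couple naturally — phenytoin's autoinduction of
CYP2C9 is what brings its simulated steady state into the therapeutic range.

**Driver concentrations.** Reversible modifiers are evaluated per expressing
organ with the *local* unbound concentration (liver drivers for hepatic
shares, gut drivers for gut-wall shares), which is what makes oral
first-pass interactions stronger than systemic exposure alone would
suggest. The shared turnover pool, being one state per enzyme, is driven by
the unbound liver concentration; a per-organ pool split was considered and
rejected to keep one pool per enzyme in the reported trajectories.

**Washout.** With the shipped $k_{deg} = 0.0158\,h^{-1}$ (pool half-life
~44 h), withdrawing a chronic phenytoin-like induction stimulus returns the
pool to within 10% of baseline in $\ln(10\,\Delta E/E_0)/k_{deg}$ — about
8 days at the exposure the shipped phenytoin model reaches at 100 mg
three-times-daily, inside the clinically reported 7–10-day window. That
formula assumes the stimulus stops sharply; in a full timeline simulation
the inducer's own elimination tail keeps partial stimulus alive for another
1–2 days, so whole-body recovery lands near 10–11 days. The package tests
the turnover-level statement (where the formula is defined) and exposes the
whole-body behaviour through scenario simulations.

## Virtual populations and genotype

A population spec fixes demography (ethnicity label selecting mean
weight/height — 73 kg/176 cm European, 57 kg/165 cm Japanese male), an age
range, independent log-normal variability (median-1 factors, geometric CV)
on anthropometrics and per-enzyme baselines, genotype phenotype frequencies,
and a seed. Each individual draws from a seed derived from its index, so
populations are bitwise reproducible and order-independent. Phenotypes
replace $E_0$ by reference concentrations: CYP2C19 normal / intermediate /
poor metabolisers at 0.76 / 0.40 / 0.01 µmol/L, CYP3A5 expressers /
non-expressers at 0.68 / 0.04 µmol/L. The independence assumption (no
correlation matrix across parameters) is deliberate: the outputs the
platform reports are means, SDs and attainment fractions, for which
independent log-normals are the standard first-order population model.

## Scenarios, timelines, dose search

Clinical timelines use the transplant day convention: day 0 is the first
victim dose; perpetrator courses may start on negative days (conditioning)
and stop before the victim starts — residual induction then decays by
enzyme turnover, which is how a phenytoin course on days −5…−1 still
depresses a cyclosporine trough measured on day +6. Troughs are evaluated
pre-dose at 24 h × day. The dose search walks an ascending list of
clinically dosable amounts and recommends the smallest whose population
criterion lands inside the therapeutic window — population mean by default,
attainment fraction as the robustness alternative (never more permissive
than the mean at a window edge). Windows ship with the library: cyclosporine
200–400 ng/mL, tacrolimus 5–15 ng/mL, sirolimus 3–8 ng/mL, voriconazole 1–5
µg/mL, posaconazole ≥0.7 µg/mL, itraconazole ≥0.5 µg/mL, phenytoin 10–20
µg/mL, busulfan 900–1,350 µM·min per dosing interval (the lower-bound
variant 900–1,500 that also circulates is configurable; the shipped default
follows the majority convention).

## The drug library is a curated fixture

Thirteen compound files ship with the package. Their mechanism assignments
(who inhibits/induces what, and by which mechanism — e.g. irreversible
CYP3A4 inactivation by voriconazole and tacrolimus, irreversible CYP2C19
inactivation by omeprazole, phenytoin induction of CYP2C9/2C19/3A4/UGT1A4/
GSTA1, letermovir's mixed inducer-inhibitor profile) are structural facts
the tests assert. The numeric constants (CLint, Ki, kinact/KI, Emax/EC50)
are curated literature-typical values with per-field provenance comments,
chosen once from therapeutic-concentration reasoning; they are fixtures for
exercising the machinery, not validated estimates, and the test suite
treats them accordingly. Induction EC50 values are expressed on the
unbound-plasma scale. Fosaprepitant is an intravenous prodrug converting to
aprepitant with a fast first-order rate (half-life ~5 min); aprepitant
carries the CYP3A4 interaction specs.

## Synthetic data

`generate_observed_profile()` stands in for digitised literature profiles:
it simulates a known truth compound, samples it at stated times, and applies
multiplicative log-normal noise (log-SD equal to the stated CV), emitting
the dataset together with its generating truth. What this emulates well:
sampling sparsity, decade-spanning concentrations, multiplicative assay
error. What it does not emulate: model misspecification (the fitted model
family *is* the generating family), inter-study heterogeneity, below-limit
censoring patterns of real assays (an LLOQ exclusion exists, but the
generator places no values below it by design), or digitisation bias.
Passing recovery tests therefore demonstrate estimator correctness, not
that real literature data would identify the same parameters.

## Numerical choices

* Integration: `deSolve::lsoda`, rtol 1e-6 / atol 1e-9 (fits use 1e-5/1e-8);
  all integrator settings are arguments.
* Dose events force integrator restarts; output rows at an event time report
  the pre-event state, and the mass-balance audit accounts doses strictly
  after their event time accordingly.
* AUC is trapezoidal on the output grid; intravenous AUC-to-infinity adds a
  log-linear tail from the final 20% of the interval. Resolving the venous
  mixing transient after a bolus (time-constant ≈ venous volume / cardiac
  output ≈ 40 s) needs a log-spaced early grid, which the oracle checks use.
* Mass balance closes to solver precision (≲1e-4 %) across the library; the
  audit tolerance used in tests is 0.5%.
* Report ratios round half-away-from-zero to one decimal; values landing
  exactly on a 0.05 boundary are flagged rather than silently rounded. Raw
  ratios are always retained.
* The variability-scaled (Guest) acceptance band uses
  $L = (\delta + 2(R_{obs}-1))/R_{obs}$ for $R_{obs} \ge 1$ and extends to
  $R_{obs} < 1$ by reciprocal symmetry, preserving the induction/inhibition
  duality; $\delta = 1.25$ gives (0.8, 1.25) at no interaction and the band
  stays strictly inside the two-fold window on [0.5, 2].
* Fitting: sum of squared log-concentration residuals (PK spans decades),
  LLOQ-excluded; multi-start bounded `nlminb` from a Latin-hypercube design
  in log-parameter space, best of starts, reproducible by seed. Default 8
  starts; the recovery test suite uses 3 (and 20 noise replicates of a
  12-point, 24-hour design), sizes chosen as a deliberate compromise for a
  routinely runnable suite.

## Known limitations

Perfusion-limited tissues only (no permeability-limited brain or tumour
compartments); no protein-binding displacement interactions; one enzyme pool
per enzyme rather than per organ; no correlation structure in population
variability; ionisation absent from the partition model (handled per
compound via effective lipophilicity); transporter interplay is represented
as inhibitable clearance pathways, not vectorial transport; and absolute
exposure predictions for the library drugs inherit the fixture status of
their parameters. The arithmetic of the published interaction report — the
trough-ratio table, the percent changes, the fold-change list — is
reproduced exactly from printed means; the simulation engine is verified
against closed forms and invariants rather than against the original
software's trajectories, which depend on a proprietary parameter database.
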