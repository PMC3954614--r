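---
title: "A regulated kinetic-metabolic model of CHO batch culture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A regulated kinetic-metabolic model of CHO batch culture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chometab)
```

## The model

`chometab` simulates a Chinese hamster ovary (CHO) cell batch culture as a
system of 46 ordinary differential equations over a lumped central-carbon
and energy metabolism network with 35 reactions: glycolysis (5 lumped
steps), the oxidative and non-oxidative pentose phosphate pathway, the TCA
cycle, glutaminolysis, anaplerosis/cataplerosis (pyruvate carboxylase,
malic enzyme), three lumped amino-acid catabolic groups entering the TCA
cycle through pyruvate, oxaloacetate, alpha-ketoglutarate and succinate,
respiration with an explicit proton-leak branch, energy buffering (creatine
and adenylate kinases), biomass synthesis and recombinant antibody
synthesis. The state comprises viable cell density, the mAb titer, 23
extracellular metabolites (glucose, lactate, ammonium, 20 amino acids) in
mM and 21 intracellular pools in nmol per 10^6 cells. Seven reactions
(LDH, GLNS, GLDH, AlaTA, ASTA, CK, AK) carry independent forward and
reverse maximum rates, giving 42 maximum-rate parameters; together with 48
affinity constants and 5 regulatory constants the model has 95 kinetic
parameters, verifiable with `validate_network()`.

Every flux is a maximum rate multiplied by dimensionless factors: one
Michaelis–Menten saturation term per kinetic substrate, a nucleotide-ratio
driving force, and the enabled regulation factors. Cofactors act through
the ratios ATP/ADP, NADH/NAD and NADPH/NADP rather than absolute pools, so
the energy and redox state coordinates flux distribution; the summed
moiety pools (ATP+ADP+AMP, NAD+NADH, NADP+NADPH, phosphocreatine+creatine)
are conserved by construction, which the test suite asserts on the
stoichiometric matrix and along trajectories. Uptake of extracellular
nutrients is carried by the first intracellular enzymatic step (e.g. the
hexokinase lump consumes extracellular glucose directly), reflecting the
view that transporters are not rate-controlling at media concentrations.

Five glycolytic regulation terms can be toggled as scenarios
(`none`, `I`, `I+II`, `all`): hexokinase product inhibition by G6P (I),
phosphoglucose-isomerase inhibition by PEP (II), phosphofructokinase
inhibition by G6P (III), pyruvate-kinase activation by F6P (IV) and
inhibition of the forward lactate-dehydrogenase reaction by extracellular
lactate (V). Each term is a hyperbolic factor in (0, 1]; the package
default scenario is `I+II`, the most parsimonious formulation that
reproduces the regulated behaviour. Mass balances:

* cells: dXv/dt = mu * Xv, with mu the growth-reaction flux (1/h);
* extracellular C (mM): dC/dt = s * v * Xv * 1000;
* intracellular c (nmol/10^6 cells): dc/dt = s * v * 1e6 − mu * c for
  carbon intermediates (growth dilution), without the dilution term for
  cofactor moieties;
* titer (mg/L): d[mAb]/dt = v_mAb * Xv * 1000 * MW, with MW = 150 kDa.

Fluxes are in mmol per 10^6 cells per hour. Cumate induction at 48 h is an
event: before it (and throughout a non-induced culture) the mAb maximum
rate is scaled by the clone's leaky fraction.

## Numerical implementation

The right-hand side and an adaptive Dormand–Prince RK45 integrator are
compiled (Rcpp); a pure-R flux engine (`flux_vector`,
`state_derivative`) defines the reference semantics and the two paths are
tested against each other to 1e-12, and against an independent fixed-step
RK4 oracle. Default tolerances are rtol 1e-7, atol 1e-9; induction is
handled by restarting the integration at the event time; small negative
excursions are clamped at zero after accepted steps (at tolerance level).
The explicit scheme requires the fastest pool turnover to stay well above
its stability floor; the bundled intracellular pool sizes are therefore
set larger than literal cellular contents (e.g. adenylate total 1338 nmol
per 10^6 cells) while the physiologically meaningful quantities — the
nucleotide ratios (ATP/ADP about 10, NADH/NAD 0.03–0.07) and all fluxes —
are at reported levels. The scale was fixed by rescaling every
intracellular pool together with its affinity and regulatory constants, a
transformation that leaves fluxes, ratios, depletion times and the clone
phenomenology essentially unchanged while multiplying the fast time
constants; one 144-h batch simulation costs a few tens of milliseconds on
a single core. Only ratios and saturation fractions enter the rate laws,
so this conditioning choice does not alter the model's driving forces.

## Reconstructed default parameters

The published parameter tables for this model family are not available, so
the bundled defaults are an explicit, documented reconstruction. They are
generated by inverting each rate law at a mid-exponential operating state
(`chometab:::.op_state()`) against design fluxes with the printed orders of
magnitude: glucose uptake 7.7e-5, glycolytic flux 1.4e-4, net lactate
production 8.7e-5, pyruvate dehydrogenase 4.3e-5 mmol/(10^6 cells)/h,
growth 0.035 1/h, an ATP turnover near 1e-3, and a proton-leak share of
15% of oxygen uptake. This construction makes the design point an exact
fixed point of the rate laws, guarantees strictly positive parameters, and
yields batch trajectories with the reported phenomenology: maximum density
about 3e6 cells/mL, glutamine depletion before 120 h with growth arrest at
depletion, glucose above 5 mM at harvest, glutamate and alanine secretion,
and ammonium around 3–4 mM. Where the sources state no value, media-level
amino-acid concentrations and affinity constants were fixed once at
typical chemically-defined-medium and BRENDA-range magnitudes and not
revisited.

Two reconstruction choices deserve emphasis:

* **Affinity-constant budget.** The 48 affinity constants comprise 44
  substrate/product Km values (the lumped amino-acid group reactions use
  one pooled Km; growth and mAb synthesis use a single shared per-amino-acid
  Km, plus a dedicated glutamine constant for growth) and 4 nucleotide-ratio
  half-saturation constants (respiration NADH- and ADP-side, proton leak).
  All other cofactor-ratio driving forces use the parameter-free form
  r/(1+r), i.e. a unit reference ratio.
* **Glutamine-depletion coupling.** A smooth Hill-type threshold switch on
  extracellular glutamine (midpoint 0.3 mM, exponent 4) gates the uptake
  direction of alanine aminotransferase *and* of lactate dehydrogenase.
  The latter extends the published wiring (which names only alanine): the
  reported post-depletion lactate consumption is attributed to the same
  depletion coupling, and without it the model self-stabilises on the LDH
  equilibrium manifold — net lactate flux approaches zero from above but
  can never turn negative, because lactate is the only extracellular fate
  of the pool. With the gate, clones with a large reverse-LDH capacity
  (the high producer) show a genuine lactate switch while the parental
  line keeps producing lactate, as observed.

## Calibration

`fit_culture()` minimises the weighted sum of squared residuals
(WSSRES) — squared differences between replicate-mean measurements and
simulated values, weighted by the inverse pooled per-variable replicate
variance — by Levenberg–Marquardt iteration on log10-scaled parameters
with bounds start/100 to start*100 (rates are positive and span decades).
Confidence intervals are asymptotic linearised intervals (t-quantile times
the standard error from the weighted residual Jacobian, with the error
variance re-estimated as WSSRES/(N−p)), the same convention as MATLAB's
`nlparci`; prediction envelopes use the delta method on the same
linearisation (`predict(fit, interval = "confidence")`). A consequence of
re-estimating the error variance is that intervals are invariant to a
common rescaling of the variances — the test suite asserts this rather
than a square-root widening. `screen_parameters()` ranks parameters by
their one-at-a-time effect on the objective and freezes those whose
normalised WSSRES never deviates by 15% or more; `compare_fits()` performs
per-parameter two-sided Wald z-tests between two calibrated cultures, with
alpha = 0.1 by default and no multiplicity correction (raw p-values are
reported, matching the source convention; this is documented rather than
hidden).

## Sensitivity analysis

`global_sweep()` varies each parameter one at a time over a relative grid
spanning −85% to +300% (default grid −85, −50, −25, −10, 0, +10, +25, +50,
+100, +200, +300 percent; only the span is prescribed, the intermediate
points are a package choice) and reports WSSRES normalised to the
unperturbed value, exactly 1 at 0% by construction. `partial_sweep()`
restricts the objective to one measured variable; the unnormalised
per-variable maps sum to the unnormalised global map because the objective
is additive. The sweep data (matrix CSV via the CLI) is the contract; the
heat-map rendering (`plot()`) is cosmetic.

## Biomarker panel

`biomarker_panel()` evaluates, per time point: the lactate-to-glucose
ratio (net LDH over HK), the pyruvate branch point ((PDH+PC) over the
positive inflows to the pyruvate pool among PK, SAL, the lumped
pyruvate-family transaminase, malic enzyme and reverse AlaTA), the
percentage of pyruvate derived from glucose, the TCA-entry contribution
shares of glucose (PDH), glutamine (GLDH), other amino acids (lumped
transaminase + aspartate exchange) and pyruvate carboxylase — all entry
fluxes clamped at zero when running backwards, so shares stay in [0, 1]
and sum to one — the TCA cycle flux (the SDH/FUM lump), glutamine uptake
(forward minus reverse GLNS), the ATP turnover rate (PGK + PK + SCOAS +
reverse GLNS + forward CK + reverse AK + 2·(P/O)·resp, substrate-level
terms clamped to their ATP-forming direction), and the ATP partitioning
percentages for biomass (0.00043·3.78·mu over turnover, the two constants
kept verbatim as caption constants with units left symbolic) and antibody
synthesis (4·v_mAb over turnover). The published caption divisors for the
two percentages are garbled in the source; the only reading that yields a
percentage — division by the ATP turnover — is implemented.
`induction_ratio_panel()` normalises an induced culture's panel by its
non-induced control at matching times, reporting missing (not infinite)
entries where the control is zero.

`mab_carbon_fraction()` is the worked carbon-load estimate: the carbon
mass flux into antibody over total carbon accumulation. Its defaults take
the published inputs verbatim — productivity 1e-6 mmol/(10^6 cells)/h,
growth 0.04 1/h, dry cell weight 350 pg/cell and a molecular weight of
150 g/mol. That molecular weight is printed as a "cellular molecular
weight" and is inconsistent with a 150 kDa antibody; taken literally it
gives about 1.4%, consistent with the published "at most 5%" bound,
whereas 150 kDa would give >90% and contradict the published conclusion.
The default therefore follows the printed sentence, and the parameter is
exposed so users can supply their own bookkeeping.

## Synthetic experiments

`generate_experiment()` emulates the emulated assay campaign: seed
2e5 cells/mL in 30 mM glucose and 4 mM glutamine, sampling every 24 h for
6 days, optional induction at 48 h, duplicate flasks, multiplicative
log-normal noise with 5% CV (unbiased in the log domain, with a small
additive floor so near-zero signals keep a finite spread — the true assay
noise structure is unreported; 5% CV is a fixture convention).
`reference_panel()` reproduces the five-culture design: parental, low- and
high-producer each with and without induction, sharing clone parameters
within a clone. The bundled clone specifications move the attested
parameters in the attested directions (reverse LDH and ATPase for the
low producer; additionally forward ASTA and PDH for the high producer,
whose +75%-and-above PDH shift drives the increased net pyruvate flux into
the TCA cycle) plus fixture-level adjustments — larger respiratory and
TCA-trunk capacity and maintenance ATPase for the high producer — aligned
with its reported higher oxygen uptake and global TCA activity. These
magnitudes were fixed once against the qualitative stated-world checks
(lactate switch, lactate/glucose ratio below one, glucose above 5 mM,
ATP/ADP near 10) and are not fitted quantities; a green fixture test
establishes internal consistency of the generator, not agreement with any
laboratory culture.

## Known limitations

* Thermodynamic (Haldane) consistency is not enforced; lumped reactions
  carry independent forward/reverse maximum rates.
* Cell death/lysis is not modelled; the density plateau emerges from
  glutamine-dependent growth kinetics alone.
* Lipid precursors are excluded from the biomass equation.
* The exact algebraic rate laws and parameter values of the source model
  are a reconstruction constrained by the printed counts, named fluxes and
  qualitative statements; quantitative agreement with the published
  per-flux tables is not claimed.
* The per-parameter Wald comparison reports raw p-values; with ~30
  simultaneous tests users should expect false positives at the nominal
  rate.
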