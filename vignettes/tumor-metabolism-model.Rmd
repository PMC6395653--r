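---
title: "A kinetic model of tumor central carbon metabolism and metabolic therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of tumor central carbon metabolism and metabolic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warburgsim)
```

## The model

`warburgsim` simulates the growth of an LL/2 Lewis lung carcinoma xenograft
as a metabolically structured population of tumor cells perfused by a
capillary network. The tumor is treated as two coupled compartments:

* **blood** — the capillary micro-environment, a perfectly mixed vessel of
  volume $V_{blood}$ continuously fed at flow $F_{in}$ (mL/h) with inlet
  composition $C_0$ and drained at $F_{out}$;
* **cell** — a single intracellular pool holding the metabolites of central
  carbon metabolism.

The state is $(C, m, X, V_{blood}, V_{tumor})$: blood concentrations (mM),
intracellular concentrations (mM), tumor cell amount ($10^6$ cells),
capillary volume (mL) and total tumor volume (mm$^3$). Its dynamics are

$$
\begin{aligned}
\frac{dC}{dt} &= S_c\, r\, \frac{X}{V_{blood}}
  + \frac{C_0 F_{in} - C\, F_{out}}{V_{blood}} - \mu_{blood}\, C\\[2pt]
\frac{dm}{dt} &= S_m\, r - (\varepsilon_m + m)\,\mu\\[2pt]
\frac{dX}{dt} &= \mu X - k_d\,
  \frac{1-\rho^{\,n}}{k_{\rho}^{\,n}+\rho^{\,n}}\, X,
  \qquad \rho = \mathrm{NAD^+}/\mathrm{NADH}\\[2pt]
\frac{dV_{blood}}{dt} &= \mu_{blood} V_{blood}\\[2pt]
\frac{dV_{tumor}}{dt} &= \frac{dX}{dt} + \frac{dV_{blood}}{dt}
\end{aligned}
$$

where $S_c$ and $S_m$ are the stoichiometric matrices of the reactions over
the blood and intracellular species and $r$ is the flux vector. The last
equation adds a cell amount to a volume; we make it dimensionally coherent
with an explicit single-cell volume constant `v_cell` (default $10^{-6}$
mm$^3$/cell, so $10^9$ cells $\approx$ 1 cm$^3$); this is the minimal
assumption that closes the unit system and it is configurable everywhere.

The death term is kept exactly as written. For $\rho > 1$ it is *negative*:
a redox-gated survival advantage. This is deliberate and load-bearing — the
Warburg state (high NAD$^+$/NADH) accelerates net growth, and therapy acts
largely by dragging $\rho$ below 1, where the same term becomes a death
rate. We do not clamp it.

### The network

The packaged reconstruction (`ll2_network()`) covers 35 enzymatic reactions
over 52 metabolites: glycolysis, the oxidative pentose phosphate branch, the
TCA cycle, lipogenesis, oxidative phosphorylation and amino-acid metabolism,
with `Vgrowth` as the biomass reaction (amino acids + G6P + R5P + palmitate
+ ATP). Reaction-level stoichiometry is not published for this system, so
the reconstruction follows the topology of the cited CHO-cell model family;
it ships as a human-editable TSV (one reaction per row) that is the source
of truth, with an SBML export (`write_sbml()`) for interoperability.

Reconstruction choices that matter structurally:

* **Two acetyl-CoA pools.** `ACCOAm` (mitochondrial, from pyruvate
  dehydrogenase and amino-acid degradation, feeding citrate synthase) and
  `ACCOAc` (cytosolic, produced only by ATP-citrate lyase, consumed only by
  fatty-acid synthesis). This split is what makes `VACL` a single-reaction
  cut set for growth, as structural analysis requires.
* **NADP balance.** The oxidative PPP is the only NADPH source besides
  nothing — malic enzyme is modelled NAD-linked (the ME2 isoform) — and
  lipogenesis the only sink, with growth coefficients (0.28 R5P, 0.04 PALM)
  chosen so that 2 NADPH per R5P exactly covers 14 NADPH per palmitate.
  Without this balance either the PPP or malic enzyme becomes spuriously
  essential.
* **Phosphate bookkeeping.** The biomass reaction returns the phosphate
  carried by its G6P and R5P demand (0.38 Pi); without it no steady-state
  growth mode exists at all.
* **Maintenance ATPase (`VATPM`).** Non-growth-associated ATP turnover.
  Kinetically this is the energy-dissipation route that keeps the
  ADP/Pi pools turning over at Warburg-scale glycolytic flux; without it the
  adenylate and phosphate pools collapse into dead ends within days.
* **Boundary convention.** Blood metabolites are open boundary species for
  structural analysis; intracellular species are balanced at steady state.
  Reversible reactions (`VLDH`, `VFUM`, `VMDH`, `VAK`, `VALATA`, `VASPTA`)
  are split into direction pairs; deleting a reaction deletes both
  directions (enzyme-level semantics).

With these conventions the enumeration (`elementary_flux_modes()`,
Schuster-style double description; `minimal_cut_sets()`, Berge incremental
transversal) yields 581 elementary flux modes and 183 minimal cut sets for
the growth target, of which exactly six are single reactions: `VHK`,
`VG6PDH`, `VCS`, `VACL`, `VPALM`, `Vgrowth`. The total count is
reconstruction-dependent (reversibility and boundary assignments move it by
hundreds); the identity of the size-one set is the robust result, and it
includes the two drug-targeted enzymes hexokinase and ATP-citrate lyase.

### Kinetics and drug effects

Each reaction carries a generalized multiplicative Michaelis–Menten law,
$v = v_{max}\prod_s \frac{c_s}{K_s + c_s} - v_{max}^{rev}\prod_p
\frac{c_p}{K_p + c_p}$, with the saturating species listed per reaction in
the packaged parameter table. Four drugs modulate their annotated targets
multiplicatively on the *net* rate:

| drug | target | mode | half-effect $k$ (mM) |
|---|---|---|---|
| diclofenac (`DICLO`) | `VHK`, `VLDH` | inhibit | 0.01 |
| alpha-lipoic acid (`LA`) | `VPDH` | activate | 0.01 |
| hydroxycitrate (`HCIT`) | `VACL` | inhibit | 0.05 |
| metformin (`MET`) | `VATPase` | inhibit | 13 |
| metformin (`MET`) | `VNADleak` | activate | 1 |

Inhibition multiplies by $k/(k+c) \in (0,1]$, activation by
$1 + c/(k+c) \in [1,2)$. Dosing is deliberately PK-free: an arm's dose maps
to a constant inlet blood concentration (1× the drug's smallest $k$ for
standard/low, 10× for high) applied as a step from the treatment start (day
12). The METABLOC pair (lipoic acid + hydroxycitrate) uses the standard 1×
exposure — the corresponding single-agent arm only mildly slows growth, and
a 10× exposure on ATP-citrate lyase would contradict that. Metformin's
ATP-synthase half-effect (13 mM) is much larger than its dosing unit: at the
high dose it halves, rather than abolishes, ATP-synthase flux. Abolishing
it froze every treated arm within a day of dosing, which is not what treated
tumors do.

### Growth, death, and what makes the therapy arm stop

The specific growth rate is flux-linked by default,
$\mu = \mu_{max}\, r_{Vgrowth}/v_{max,Vgrowth}$, i.e. $\mu_{max}$ scaled by
the biomass reaction's saturation state ($\mu_{max} = 0.0048$/h). A
constant-$\mu$ mode exists and is the default when fitting, where $\mu$ is
itself a fitted parameter.

The calibrated defaults reproduce the study endpoints: the untreated arm
grows from 154 mm$^3$ at day 10 to about 4000 mm$^3$ at day 59 while blood
glucose in the tumor falls toward exhaustion and lactate accumulates after
an initial washout; the full-therapy arm (METABLOC + high metformin + high
diclofenac) grows nearly in parallel until about day 35 and then arrests
within ±15% of 873 mm$^3$. Three mechanisms, all emergent from the network
kinetics, produce the treated arm's delayed arrest:

1. **Precursor reserves.** Diclofenac cuts hexokinase 11-fold, starving the
   PPP; growth continues on stored pentose and lipid pools (`R5P`, `PALM`
   start at 1.0 and 0.5 mM) that growth-dilution exhausts over roughly three
   weeks.
2. **A glutamate ramp.** Glutaminolysis continues under therapy; glutamate
   accumulates toward the high-$K_m$ glutamate dehydrogenase (Km 4 mM), so
   NADH production rises slowly over weeks.
3. **Redox crossing.** With lactate dehydrogenase inhibited, the rising
   NADH cannot be discharged into lactate; once production exceeds the
   respiratory capacity, NAD$^+$/NADH slides below 1 and the death term
   changes sign. The volume then approaches the plateau as a damped
   oscillation: it enters the 873 ± 15% band at day ~35, stays inside it to
   day 59, and the strict weekly-change-below-1% condition holds from about
   day 50.

The same machinery produces the reversed-Warburg flux signatures: treated
tumors respire more than late-stage controls and their redox ratio falls
several-fold. One signature is *not* reproduced: the late lactate
dehydrogenase flux in the treated arm stays marginally positive (~3% of the
control flux) instead of turning negative. Because the drug factor
multiplies the net reversible rate, an 11-fold inhibition scales secretion
and uptake equally, and the treated steady state retains just enough
glycolytic and alanine-derived pyruvate to keep the forward term ahead.
Reproducing net lactate uptake would need either direction-asymmetric
transport inhibition or a different treated pyruvate balance; we record the
discrepancy rather than distort the drug model.

A related, genuine limitation: metformin's dose response is only monotone
when the other drugs are present. Alone, its ATP-synthase inhibition
indirectly trims glycolysis (hexokinase is ATP-dependent), which *raises*
NAD$^+$/NADH and with it the survival advantage — a net growth benefit of a
few percent at high dose. On the full-therapy background, where diclofenac
has already closed that channel, the dose response is monotone to within a
~1–2% transient.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), relative tolerance
  $10^{-6}$, absolute $10^{-9}$, split at the treatment-start discontinuity.
  The right-hand side is compiled C (the standard deSolve pattern); a plain-R
  reference implementation (`derivatives()`) is retained and the test suite
  checks the two against finite differences of integrated trajectories.
* Negative states: concentrations are clipped at zero for rate evaluation
  inside the solver; output states below $-10^{-6}$ mM abort with a
  diagnostic naming the first offending time (near-zero species routinely
  overshoot to $\sim -10^{-8}$ numerically at these tolerances, so the strict
  $-10^{-9}$ bound would false-alarm).
* Initial conditions: $V_{tumor} = 154$ mm$^3$ at day 10, 10% capillary
  blood; blood starts at the inlet composition except lactate (2.5 mM versus
  1.5 mM inlet, representing pre-perfusion local accumulation — this is what
  produces the initial washout dip before secretion wins).
* Time is integrated in hours; all interfaces use days post-inoculation.
* Cofactor pools (NAD(H), adenylates, CoA, NADP(H), FAD(H$_2$)) are
  conserved moieties with no synthesis reaction, so growth-dilution shrinks
  them over the 49-day run; the kinetics are parameterised to stay
  functional across that range. An earlier design that injected cofactor
  synthesis into the biomass reaction was rejected because net production of
  a conserved moiety destroys steady-state feasibility and with it the
  structural analysis.

## Parameter estimation

`fit_tumor_model()` minimises the weighted least-squares objective
$\sum_n \sum_t \left((Y^{exp}_{n,t} - Y_{n,t}(p))/\sigma_{n,t}\right)^2$
over the sensitive parameters $F_{in}$, $F_{out}$ and $\mu$ under box
bounds (L-BFGS-B, optional seeded multi-start, optional Nelder–Mead
polish). Simulation failures inside the optimizer return a large finite
penalty. $\sigma$ comes from the cohort SD at each time, floored at 1
mm$^3$. When $F_{out}$ is not among the fitted parameters it follows
$F_{in}$ (the printed system has a single flow $F$).

What tumor volume can and cannot identify, at the calibrated operating
point: $\mu$ is strongly identified (noise-free recovery is exact to
$<10^{-4}$ relative, and 10%-noise cohorts recover it within 15% in
essentially every replicate). The two flows are identified in their
*difference* direction but are nearly unidentifiable in their common scale
— scaling supply and washout together barely changes the volume trajectory
while substrates are non-limiting. Profiling the objective along that
direction shows a curvature hundreds of times flatter than the marginals,
which puts the statistical spread of the flow estimates at tens of percent
under 10% measurement noise. `profile_sensitivity()` exposes exactly this
picture to users; fitting lactate or glucose series alongside volume (the
multi-observable hook in `wls_objective()` accepts any simulator) is the
principled remedy.

## The synthetic cohort generator

`generate_cohort()` emulates the in vivo design: 10 mice per arm, treatment
from day 12, calipering every 3.5 days from day 10 to 59, initial volumes
$\mathcal{N}(154, 16^2)$ mm$^3$ truncated at zero, a lognormal per-mouse
growth-rate multiplier (mean 1, CV 8% — chosen to reproduce the visual
spread of per-animal growth curves) and multiplicative lognormal caliper
noise (CV 5%; caliper error scales with size). Everything is reproducible
from one integer seed, and the provenance sidecar written by
`write_cohort()` records design, seed and ground-truth parameters.

What passing cohort-based tests does and does not show: the generator's
mice are random perturbations of the deterministic model, so estimation
tests demonstrate self-consistency of the pipeline, not robustness to model
misspecification. Real cohorts carry inter-animal pharmacokinetic
variation, measurement schedules that slip, and early deaths, none of which
are emulated; the lethal-volume censoring flag (off by default) is the only
concession to the last of these.

## Worked example

```{r example, eval = FALSE}
model <- ll2_model()

# structural analysis
cs <- minimal_cut_sets(ll2_network(), "Vgrowth")
essential_reactions(ll2_network(), "Vgrowth")

# the two calibrated arms
ctrl <- simulate_tumor(model, tumor_scenario("pbs"))
ther <- simulate_tumor(model, tumor_scenario("metablocs_full"))
compare_arms(list(pbs = ctrl, metablocs_full = ther))
autoplot(ther)

# a synthetic cohort and a fit to it
cohort <- generate_cohort(cohort_design("pbs", seed = 1), model = model)
fit <- fit_tumor_model(summarize_cohort(cohort), model = model, seed = 1)
tidy(fit)
```

Problem sizes used throughout the package's own test suite: the packaged
35-reaction network for structural analysis (seconds), 49-day simulations
(well under a second each with the compiled right-hand side), 20-replicate
recovery experiments with 10-mouse cohorts, and brute-force structural
oracles on random networks of up to 8 reactions.
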