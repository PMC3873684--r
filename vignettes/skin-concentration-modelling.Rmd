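---
title: "Predicting membrane and skin concentration from permeation time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting membrane and skin concentration from permeation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinperm)
```

## The problem

For topical drugs and cosmetics the pharmacologically relevant quantity is
usually the concentration of the compound *inside* the skin, not the amount
that crosses it. Measuring membrane concentration directly is awkward — one
membrane yields one terminal data point, and washing the surface either
strips drug out of the membrane or leaves formulation on it. Permeation
experiments in Franz diffusion cells, by contrast, are routine and yield a
whole cumulative-amount time course per membrane.

`skinperm` implements the modelling chain that converts a permeation time
course into a steady-state membrane- or skin-concentration estimate:

1. closed-form Fickian diffusion solutions for a homogeneous membrane
   (`conc_profile()`, `cumulative_amount()`, ...),
2. a two-layer stratum-corneum (SC) / viable-epidermis-and-dermis (VED)
   skin model — steady-state algebra plus a transient Crank–Nicolson
   solver (`ss_amounts()`, `solve_bilayer_pde()`),
3. nonlinear least-squares estimation of the partition coefficient $K$ and
   diffusion coefficient $D$ from the time course (`fit_onelayer()`,
   `fit_twolayer()`),
4. steady-state concentration prediction and a linear cross-membrane
   calibration that maps cheap artificial-membrane (silicone) predictions
   onto skin concentrations (`theoretical_conc()`, `calibrate()`,
   `predict_skin_conc()`),
5. a virtual Franz-cell experiment (`simulate_experiment()`) that serves as
   the package's synthetic-data generator and as the template for reducing
   real sampled-receiver data (`reconstruct_cumulative()`).

## One-layer model

Diffusion through a homogeneous membrane of thickness $L$ obeys Fick's
second law $\partial C/\partial t = D\,\partial^2 C/\partial x^2$ with a
constant donor at the upper face, $C(0,t) = K C_v$, a perfect sink at the
lower face, $C(L,t)=0$, and an initially empty membrane. $K$ is the
vehicle→membrane partition coefficient and $C_v$ the donor concentration.
The concentration is the classical Fourier series

$$C(x,t) = K C_v\Big[1-\tfrac{x}{L} -
  \tfrac{2}{\pi}\sum_{n\ge1}\tfrac1n \sin\tfrac{n\pi x}{L}
  e^{-D n^2\pi^2 t/L^2}\Big],$$

and the cumulative amount permeated per unit area is the lag-time solution

$$Q(t) = K L C_v\Big[\tfrac{Dt}{L^2}-\tfrac16-
  \tfrac{2}{\pi^2}\sum_{n\ge1}\tfrac{(-1)^n}{n^2}
  e^{-D n^2\pi^2 t/L^2}\Big].$$

Two derived facts carry the whole method:

* the late-time slope of $Q$ is $P C_v$ with $P = K D/L$, and its $t$-axis
  intercept is the lag time $L^2/6D$ — so a permeation curve identifies
  both $K$ and $D$ (given $L$);
* the steady-state *mean* membrane concentration is
  $\bar C_{ss} = K C_v/2$ — independent of $D$ and $L$. The partition
  coefficient alone converts a permeation experiment into a membrane-load
  prediction.

Series are truncated adaptively (next term below $10^{-12}$ of the running
sum, hard cap 500 terms); at $t=0$ the exact limits are returned instead of
summing, so the initial and boundary conditions hold to the last bit.

## Two-layer skin model

Skin is modelled as SC (thickness $L_{sc}$, default 15 µm) on top of VED
(default 500 µm — the VED thickness is rarely reported and should be set
from histology when known). Each layer has its own $K_i$, $D_i$ referenced
to the vehicle; layer permeabilities $P_i = K_i D_i / L_i$ combine like
conductances in series, $1/P_{tot} = 1/P_{sc} + 1/P_{ved}$.

At steady state the concentration falls linearly within each layer and the
drop across each layer is proportional to its resistance $R_i = 1/P_i$,
giving the SC-side interface concentration
$C_b = K_{sc} C_v R_{ved}/(R_{sc}+R_{ved})$. Integrating the
piecewise-linear profile gives the layer loads
$M_{sc} = L_{sc}(K_{sc}C_v + C_b)/2$ and $M_{ved} = L_{ved} C_b'/2$ and the
average skin concentration $\bar C_{ss} = (M_{sc}+M_{ved})/L_{tot}$.

**Interface condition.** Across the SC/VED boundary we enforce equal
chemical potential, $C_{sc}/K_{sc} = C_{ved}/K_{ved}$ (so the VED-side
interface concentration is $C_b' = C_b\,K_{ved}/K_{sc}$), together with
flux continuity. This is the unique convention under which the series-
resistance formula holds and under which two identical layers reduce
exactly to the one-layer model — both reductions are asserted in the test
suite. The package exposes the average concentration through two
independent code paths (resistance form in `ss_amounts()`, permeability
form in `ss_mean_conc_twolayer()`) that agree to machine precision and act
as mutual checks.

**Transient solver.** `solve_bilayer_pde()` integrates the coupled layer
equations with Crank–Nicolson finite differences on the potential-like
variable $u = C/K$, which is continuous across the interface; the
interface is a shared finite-volume node, making the scheme conservative —
cumulative influx minus efflux equals stored mass to machine precision
(`mass_balance_error()`). Defaults: 201 nodes per layer; the time step
starts at the diffusion-number limit ($D\,\Delta t/\Delta x^2 \le 5$) and,
once the start-up boundary layer is resolved, grows geometrically at 1% of
elapsed time. A fixed diffusion-number step would need $\sim10^7$ steps to
reach $20\,L^2/D$; the growing step reaches it in under $10^3$ while
keeping the cumulative-amount error against the analytic series below
$10^{-3}$ relative on $[0.05, 5]\,L^2/D$ (asserted in the tests).

## Parameter estimation

`fit_onelayer()` fits the composite parameters $KL$ and $D/L^2$ (the
quantities the curve actually identifies) by Levenberg–Marquardt on the
log scale, which enforces positivity. The objective is the unweighted sum
of squared residuals of cumulative amounts; optional weights are exposed.
Starting values come from the late-time asymptote (slope → $P C_v$,
intercept → lag time) and are surrounded by a seeded Latin-hypercube
multi-start spanning four decades (8 starts by default; lowest SSR wins,
ties broken by the smaller log-parameter norm). With the membrane
thickness fixed, physical $K$, $D$ and $P$ are reported.

`fit_twolayer()` consumes a full-thickness curve and a tape-stripped-skin
curve (SC removed; modelled as the VED layer alone). By default all four
parameters are fitted jointly — the stripped curve against the one-layer
series, the full curve against the two-layer PDE (101 nodes per layer
inside the optimiser; the reported fit is re-evaluated at 201) — after a
sequential initialisation (VED from the stripped curve, then SC). A purely
sequential mode is available. Identifiability is asymmetric: $P_{tot}$ is
pinned tightly by the data, while the individual SC parameters are weak
when the SC is not strongly rate-limiting; the tests assert ≤10% error on
$P_{tot}$ but allow 25% on $K_{sc}$, $D_{sc}$ at 5% assay noise.

A practical identifiability caveat, visible in the synthetic studies: if
the membrane lag time falls far below the first sampling time (a 68 µm
silicone sheet has a lag of seconds), the curve is effectively a straight
line and only $P = K D/L$ is well determined — $K$ and $D$ separate only
through the tiny intercept, and noise inflates both. The noisy recovery
studies therefore use a skin-like membrane (500 µm, $D = 10^{-7}$ cm²/s,
lag ≈ 1.2 h) whose lag sits inside the 0.25–8 h sampling window. For fast
membranes, sample earlier.

## Prediction and cross-membrane calibration

`theoretical_conc()` turns a fit into the steady-state mean concentration
($K C_v/2$ for one layer; the two-layer average otherwise) plus its
donor-normalized form $\bar C_{ss}/C_v$. Normalized predictions from an
artificial membrane correlate linearly with observed skin concentrations
across a compound series; `calibrate()` fits that line by ordinary least
squares (optionally through the origin, for series showing a 1:1
proportionality) and `predict_skin_conc()` applies it. Whether such a
calibration includes an intercept is a data question; both variants are
provided and the default keeps the intercept.

## The virtual Franz cell

`simulate_experiment()` emulates the standard sampled Franz-cell protocol:
receiver volume 6.0 mL, diffusion area 1.77 cm², and at each scheduled
time a 400 µL aliquot is withdrawn for assay and replaced with fresh
buffer. The receiver concentration therefore under-counts cumulative
permeation, and `reconstruct_cumulative()` applies the exact inverse
correction $Q_n = (C_n V_r + V_s\sum_{i<n}C_i)/A$. Assay noise is
multiplicative lognormal with mean 1 and configurable CV (additive
Gaussian optional) — multiplicative noise matches how chromatographic
assay error scales with concentration. Donor depletion is off by default,
matching the constant-donor assumption of the analytical models, and can
be switched on (quasi-static approximation) to stress-test fitting bias.
The simulator reports the receiver:donor concentration ratio and warns
above 10%, where the sink assumption behind all the closed forms becomes
questionable.

What the generator deliberately does **not** emulate: appendageal (hair
follicle) transport pathways, metabolism, extraction losses, assay
calibration drift, or inter-animal variability beyond the per-sample
noise. Passing round-trip tests on this generator demonstrates that the
estimation chain is self-consistent, not that real skin obeys a two-layer
Fickian model.

### The fixture panel

`make_fixture_panel()` builds a four-compound synthetic study patterned on
a homologous ester series of increasing lipophilicity (labelled MP, EP,
PP, BP) at donor concentrations 10, 5, 1 and 0.5 mM, each crossing a
silicone-like membrane (68 µm), full-thickness skin and stripped skin.
The parameter table is synthetic, chosen once to be realistic rather than
fitted to any dataset: silicone permeabilities centred on $10^{-5}$ cm/s,
a 26-fold partition-coefficient spread against a mere 2.5-fold spread in
$D$ (so permeability contrast is partition-driven), and a rate-limiting
SC for the hydrophilic end of the series. The EP donor is 5 mM by
default with an override, since published protocols disagree between 5
and 3 mM for that compound.

```{r panel}
panel <- suppressWarnings(make_fixture_panel(seed = 1))
panel$compounds[, c("compound", "donor_mM", "K_sil", "D_sil")]
```

## Worked example

Simulate a noisy silicone-membrane experiment, fit it, and predict the
membrane concentration:

```{r example}
mem  <- membrane_spec(L = 500e-4, K = 2, D = 1e-7)  # skin-like, lag ~1.2 h
don  <- donor_condition(10)                         # 10 mM donor
cell <- franz_cell_config(noise_cv = 0.05, seed = 7)

tc  <- reconstruct_cumulative(simulate_experiment(cell, mem, don))
fit <- fit_onelayer(tc, L_fixed = mem$L, seed = 7)
fit

th <- theoretical_conc(fit)
c(conc_mM = mol_cm3_to_mM(th$conc), normalized = th$normalized)
```

## Numerical choices, defaults, limitations

* **Units.** Internally cm, s, mol/cm³ everywhere; files and constructors
  speak hours, mM (1 mM = 10⁻⁶ mol/cm³) and nmol/cm² and convert at the
  boundary.
* **Degenerate inputs.** $K = 0$ is allowed and propagates zeros through
  every path, keeping property sweeps total. Zero or all-zero time
  courses raise a no-signal error rather than returning a spurious fit.
* **Problem sizes.** The test suite and the acceptance script use 2001
  nodes for the one-layer finite-difference oracle, 201 nodes/layer for
  reported PDE solutions, 1000 random draws for the steady-state algebra
  identity, 100 random cells for the sampling-correction sweep, and 8
  noisy replicates for the recovery study — sizes at which every check
  runs in seconds on a single core while leaving the measured error far
  from its tolerance.
* **Non-goals.** Non-sink receiver boundaries in the analytic solutions,
  concentration-dependent $D$, appendageal parallel pathways, and
  uncertainty intervals on the estimates (point estimates only).
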