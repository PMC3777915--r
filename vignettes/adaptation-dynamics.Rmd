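---
title: "Adaptation dynamics on clustered chemoreceptor lattices: models and methods"
author: "chemadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptation dynamics on clustered chemoreceptor lattices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemadapt)
```

## The problem

In *Escherichia coli* chemotaxis, thousands of transmembrane receptor
dimers pack into a dense hexagonal lattice at the cell pole. Two cytoplasmic
enzymes adapt the pathway to persistent stimuli: the methyltransferase CheR
methylates inactive receptors (re-activating them) and the phosphorylated
methylesterase CheB-P demethylates active receptors. Because the receptor
substrate is clustered, the enzymes must first *localize* to the lattice —
predominantly by binding a high-affinity tether on a receptor — before they
can modify anything. A tethered enzyme reaches the modification sites of its
own dimer and its six nearest neighbors (the *assistance neighborhood*), and
by alternately binding tethers and modification sites of neighboring dimers
it can walk across the lattice without returning to the cytoplasm
(*brachiation*).

This package asks how that spatial organization shapes the *dynamics* of
adaptation: the precision of the return to baseline after a stimulus, the
size of spontaneous steady-state fluctuations in receptor activity, and the
robustness of the adapted activity to cell-to-cell variation in protein
copy numbers. It provides two coupled descriptions of the same cell:

* an **exact stochastic simulator** of enzyme kinetics on an explicit
  receptor lattice (`simulate_lattice()`), and
* a **mean-field analytical model** with enzyme localization
  (`mf_steady_state()`, `mf_noise()`), which is the limit of a single,
  maximally large assistance neighborhood (equivalently, infinitely fast
  brachiation).

## Receptor activation (MWC)

Receptor cooperativity is described by an equilibrium two-state
Monod–Wyman–Changeux model per signaling complex of $N = 6$ dimers. The
free-energy difference between active and inactive states, in units of kT,
is

$$F(m, L) = \epsilon_m\,(m_{1/2} - m) \;+\;
  N \log\frac{1 + L/K_{\mathrm{off}}}{1 + L/K_{\mathrm{on}}},
\qquad a = \frac{1}{1 + e^{F}},$$

with $m \in [0, 48]$ the summed methylation of the six dimers (each dimer
carries 0–8 methyl groups) and $L$ the methyl-aspartate concentration.
Ligand binding is assumed equilibrated (activity responds instantaneously
to $L$ and $m$), which is appropriate because methylation kinetics are far
slower than ligand (un)binding.

Defaults: $\epsilon_m = 1$ kT per methyl group, $K_{\mathrm{off}} = 18.2$ µM,
$K_{\mathrm{on}} = 3000$ µM (a Shimizu-style Tar/MeAsp calibration), and the
offset $m_{1/2}$ fixed by `mwc_calibrate()` so that a complex with $m = 6$
is exactly half active at zero ligand. With $\epsilon_m = 1$ this gives
$m_{1/2} = 6$: complexes are highly active already at low methylation, so
fully demethylated dimers remain common even at high mean activity — which
is what makes "inert" CheB-P (tethered in a fully demethylated neighborhood,
unable to act) a real feature of the simulated system.

```{r mwc}
p <- mwc_params()
p
mwc_activity(6, 0, p)       # the calibration anchor
mwc_activity(6, 100, p)     # attractant suppresses activity
```

## The lattice

`build_lattice(w, h)` tiles a rhombic patch of the triangular lattice:
every interior dimer has exactly six neighbors, dimers are grouped into
6-dimer MWC complexes (two trimers of dimers), and three complexes form the
basic hexagonal unit, so a $w \times h$-unit lattice has $18wh$ dimers. The
production scale is $20 \times 20$ units = 7200 dimers; reduced lattices
(typically $8 \times 8$ = 1152 dimers) with enzyme counts scaled by the
dimer ratio are used for routine stochastic experiments. Boundaries are
open; boundary dimers simply have smaller assistance neighborhoods. The
simulator consumes only the adjacency, complex-membership and neighborhood
maps, so the particular planar embedding is a reproducibility convention,
not a physical claim.

## The stochastic reaction system

Each dimer carries one tether site and one modification site, each holding
at most one enzyme. Enzymes are CheR and CheB-P (unphosphorylated CheB
never binds the lattice; only bulk CheB participates in the
phosphorylation cycle, driven by the mean lattice activity). The event
channels are:

1. bulk enzyme → free tether (uniform over free tethers);
2. bulk enzyme → free modification site, weighted by $1-a$ of the target's
   complex for CheR and by $a$ for CheB-P;
3. tethered enzyme → modification site of its own dimer or any assistance
   neighbor (same activity weighting); disabled beyond the own dimer in
   variant **M2**;
4. modification-site-bound enzyme → tether of its own dimer or a neighbor
   (the brachiation hand-over-hand move); likewise restricted in M2;
5. tether release (scaled down tenfold in variant **M3**) and
   modification-site release;
6. catalysis: bound CheR adds a methyl group (if below 8), bound CheB-P
   removes one (if above 0); the modification-site bond is released on
   catalysis (`release_on_catalysis`), so processivity in M2/M3 arises
   from tether residence, not from a permanently engaged product complex;
7. bulk CheB ↔ CheB-P conversion at rates $a_p \bar a$ and $d_p$.

Variants: **M1** (reference; neighborhoods + brachiation), **M2** (no
neighbor binding: no assistance neighborhoods, no brachiation — fully
processive residences), **M3** (tether unbinding slowed tenfold:
neighborhoods intact but brachiation inefficient), and **B1** (no tethering
at all: bulk enzymes bind modification sites directly with moderate
affinity — the classic well-mixed activity-dependent modification scheme;
**B2** is B1 with tenfold higher affinity).

The engine (`src/engine.cpp`) is an exact Gillespie simulation: per-complex
activities are cached and refreshed after every methylation or ligand
change; per-enzyme channel propensities are refreshed eagerly for every
enzyme whose reachable sites were touched by an event; cached aggregates
are rebuilt from scratch every 65536 events to eliminate floating-point
drift; and an internal audit verifies conservation and occupancy
consistency at the end of every run. Time-varying ligand is piecewise
constant on the recording grid (default 0.1 s), which is negligible bias
because ramp time scales (tens of seconds) vastly exceed event time scales
(milliseconds). All randomness flows through R's RNG, so a run is a pure
function of its arguments and seed.

Exactness is validated in the test suite against brute-force
continuous-time Markov chains on two enumerable micro-models: the full
M1 binding/brachiation rule set for one enzyme with frozen methylation, and
the joint methylation–occupancy chain of one CheR plus one CheB-P on a
single complex with methylation capped at one group per dimer (the cap,
`methyl_max`, is an engine parameter that exists for exactly this purpose).

## The mean-field model with localization

All receptors share the mean activity $a$. CheR exists in bulk ($R$),
tether-localized ($R^*_{tot}$, of which a fraction is also
modification-site-bound, $R^{**}$), and likewise CheB-P. Fast local binding
within the ~5 nm tether radius gives the quasi-equilibrium occupancies

$$R^{**} = R^*_{tot}\,\frac{1-a}{(1-a)+K_r}, \qquad
  B^{**} = B^*_{tot}\,\frac{a}{a+K_b},$$

with dimensionless saturation constants $K_r, K_b \ll 1$ (the local
substrate density is enormous). The state $(m, R^*_{tot}, B^*_{tot})$
evolves as

$$\frac{dm}{dt} = \frac{2N}{T_{tot}}\left[k_r R^{**} - k_b B^{**}\right],
\qquad
\frac{dR^*_{tot}}{dt} = k^{t+}_r (R_{tot} - R^*_{tot})
  - k^{t-}_r R^*_{tot}\frac{K_r}{(1-a)+K_r},$$
$$\frac{dB^*_{tot}}{dt} = k^{t+}_b B_p
  - k^{t-}_b B^*_{tot}\frac{K_b}{a+K_b},
\qquad
B_p = \frac{a_p a}{d_p + a_p a}\,(B_{tot} - B^*_{tot}),$$

where $T_{tot}$ counts receptor monomers and $B_p$ is the bulk CheB-P pool
at its phosphorylation steady state (localized CheB-P is excluded from the
phosphorylation reactions, with total CheB conserved). Unbinding from the
lattice is a two-step process — only the tether-only fraction can leave —
which makes the overall return rate to the bulk activity-dependent.

Because $dm/dt$ depends on ligand only through $a$, the adapted activity
$a_0$ is independent of $L$: the model adapts precisely, by construction of
the fully distributive (mean-field) kinetics. The steady state reduces to
one monotone scalar equation in $a$ (the localized pools solve in closed
form), solved by bisection to $10^{-14}$ and cross-checked against ODE
relaxation (`mf_relax()`).

Eliminating the localized pools casts the methylation balance in
Goldbeter–Koshland form in the *total* counts,

$$k_r R_{tot}\frac{1-a}{(1-a)+\tilde K_r} =
  k_b B_{tot}\frac{a}{a+\tilde K_b},$$

with effective constants
$\tilde K_r = K_r\,(1 + k^{t-}_r/k^{t+}_r)$ and
$\tilde K_b = K_b\,[1 + (k^{t-}_b/k^{t+}_b)(1 + d_p/(a_p a))]$
(`mf_effective_constants()`; the algebra is verified in the tests by
demanding that the reduced form reproduces the full steady state to
$10^{-8}$ across a grid of $K$ values). This is the robustness mechanism:
the *localized* enzymes operate at saturation ($K \ll 1$, making $a_0$
ultrasensitive to the localized-enzyme ratio and amplifying localization
noise), yet slow tether binding relative to unbinding inflates the
*effective* constants to order 1, so $a_0$ remains robust to the total
CheR/CheB expression ratio. In the classic well-mixed scheme those two
properties are incompatible.

## Noise: linear noise approximation

Fluctuations around the steady state follow a multivariate
Ornstein–Uhlenbeck process $d\mathbf{x} = A\mathbf{x}\,dt + B\,d\mathbf{W}$
with $B B^T = S\,\mathrm{diag}(\mathbf v)\,S^T$ assembled from the
elementary noise-carrying events: methylation/demethylation
($m \pm 2N/T_{tot}$), CheR tether exchange ($R^* \pm 1$) and CheB-P tether
exchange ($B^* \pm 1$; bulk-CheB-P fluctuations fold into this channel
after the adiabatic elimination of $B_p$). The stationary covariance solves
the Lyapunov equation $A\sigma + \sigma A^T + D = 0$ (dense Kronecker
solve with residual verification; the dimension is 3). The output variance
is $\sigma_{aa} = (\partial a/\partial m)^2 \sigma_{mm}$ with
$\partial a/\partial m = \epsilon_m a(1-a)$, and because the Lyapunov
equation is linear in $D$, $\sigma_{aa}$ decomposes *exactly* into the
contributions of the three channels by re-solving with one channel's
diffusion at a time (`activity_variance()`; the parts are required to sum
to the total to $10^{-10}$). At the defaults the localized-CheR and
localized-CheB-P parts dominate the intrinsic methylation part — the
package's quantitative statement of where the large fluctuations come
from.

The LNA is validated two ways in the suite: the Lyapunov solution against
a simulated linear OU process, and the full nonlinear chemical-Langevin
version of the mean-field model (`mf_sde_simulate()`) against the LNA
variance (within 10% at the defaults).

```{r lna}
nv <- mf_noise(meanfield_params())
nv
```

## Parameters, units, and where the defaults come from

Molecular species are counted in numbers, not concentrations; volume
factors are folded into binding rates. Energies are in kT, ligand in µM,
time in seconds. The original study's supplementary parameter tables are
not available, so the defaults are *derived from the constraints the study
states*, each documented here:

| parameter | default | constraint |
|---|---|---|
| `k_t_bind` (both species) | 1/15 s⁻¹ | measured ~15 s localization time of cytoplasmic enzymes |
| `k_m_bind_local`, `k_t_bind_local` | 100 s⁻¹ per target dimer | local reactions on 1–10 ms scales within the ~5 nm tether radius (≈1.4 ms aggregated over a 7-dimer neighborhood), fast enough that brachiation randomizes enzyme positions between catalytic events |
| `k_m_unbind_r` + `k_cat_r` = 14 s⁻¹ | $K_r = 14/700 = 0.02$ | localized enzymes deep in the saturated regime, $K \ll 1$ |
| `k_t_unbind_r` = 2.29 s⁻¹ | $k^{t+}((1-a_0)+K_r)/K_r$ at $a_0 = 1/3$ | balanced tether exchange: comparable localized and cytoplasmic enzyme numbers, which simultaneously puts $\tilde K_r$ near 1 (robust regime) |
| `k_t_unbind_b` = 1.024 s⁻¹ | same balance on the CheB-P side, including the phosphorylated bulk fraction | |
| `k_cat_r` = 2 s⁻¹ | recovery from a 1 mM methyl-aspartate step within a few hundred seconds | |
| `k_cat_b` = 1.8 s⁻¹ | calibrated against the *lattice simulation* so the simulated adapted activity sits in the typical 0.3–0.5 band at nominal expression | |
| `a_p` = 20, `d_p` = 1 s⁻¹ | phosphorylation fast relative to dephosphorylation so the feedback factor $1 + d_p/(a_p a)$ stays of order 1 | |
| `k_m_bind_bulk` = 1/60 s⁻¹ | direct bulk binding to the modification site slower than tether binding (lower affinity) | |
| copies: 140 CheR, 240 CheB per 7200 dimers | immunoblotting estimates; scaled proportionally on reduced lattices | |
| B1: $K^{B1} = 0.5$, `k_cat_b` rebalanced to $a_0 = 1/3$ | the moderate-affinity, ramp-calibrated regime; B2 divides $K^{B1}$ by 10 | |

`k_cat_b` deserves a note: the mean-field balance would put it near 1.2,
but on the lattice CheB-P is systematically less effective than the
mean-field assumption predicts — it demethylates its own neighborhood and
then sits there, partially inert, an effect the mean-field model cannot
represent (it is precisely the finite-distributivity correction). The
calibration is therefore performed on the stochastic model, and the
mean-field model, mapped from the same rates by `mf_from_rates()`
($K = (k_{m,unbind}+k_{cat})/(7\,k_{m,bind,local})$, everything else
one-to-one), consequently sits at a somewhat lower adapted activity
(≈0.21) than the simulator (≈0.5 at nominal). Both are inside the band the
analysis treats as typical. For the same reason the reduced-lattice SSA
noise is *below* the mean-field LNA prediction at matched counts: lattice
correlations blunt the localized-ratio ultrasensitivity, which is exactly
the mechanism that separates M1 from the more processive M2/M3.

## Experiment protocols

* **Steps** (`ligand_protocol("step", ...)`): 5 µM (small) and 1 mM
  (large) methyl-aspartate steps at $t = 200$ s;
  `adaptation_precision()` scores $1 - |a_{adapted} - a_{pre}|/a_{pre}$
  with $a_{adapted}$ averaged over the final 20% of the post-step window
  (the windowing is a package convention, reported with every result).
* **Exponential ramps** (`ramp_response()`): $L(t) = L_0 e^{rt}$ clipped
  to 84–620 µM; the steady ramp activity is the plateau of an exponential
  fit over the ramp's active span (mean-field: one deterministic
  integration; SSA: ensemble-averaged over seeds).
* **CheR scans** (`param_scan()`): total CheR swept at 0.25–4× nominal
  with every other parameter fixed, through the mean-field, LNA or SSA
  engine.
* **Populations** (`population_spec()`, `population_run()`): overall
  expression multipliers are log-normal (median 1, shape $\sigma_{ln} =
  0.35$, spanning ≈0.5–2×; quantile-stratified by default so 8 cells cover
  the range reproducibly). Ratio preservation is taken seriously: each
  cell's *lattice* is scaled with the multiplier (hexagonal units rounded)
  and enzymes follow at fixed density, mirroring cotranscription with
  intrinsic noise ignored. Scaling only the enzymes would change the
  enzyme:receptor ratio and invert the expression-dependence of the noise.
* **Processivity** (`processivity_rate()`): unique receptor dimers whose
  tether or modification site an enzyme occupies, counted per residence
  (revisits within a residence don't count) per unit localized time,
  pooled over enzymes. Computed online in the engine; recomputable from
  the optional contact log. Inert CheB-P (tethered where every reachable
  dimer is fully demethylated) is tracked separately and excluded from the
  localized-ratio series.

Noise statistics (`noise_stats()`) are always computed on the raw
activity series; the 30 s sliding-window smoothing (`smooth_trace()`) is
for display only. Whether to smooth before measuring variance is genuinely
ambiguous in the source material; raw was chosen and is stated here.

## Problem sizes

Routine stochastic runs use the 1152-dimer (8×8-unit) lattice with
proportionally scaled enzyme counts, 500 s burn-in and 600–1000 s recorded
at 0.1 s — each run takes well under a second of wall time, and the full
test suite (including the CTMC oracles and three-variant ensembles) runs in
about one minute. This scaled-down mode preserves the enzyme-count noise
that dominates the localized models. The well-mixed B1 model is the
exception: its fluctuations are dominated by receptor-complex shot noise,
which shrinks with cluster size, so B1 noise quantities are computed at the
production 7200-dimer scale (where B1 runs are cheap, since there is no
fast local cycling). The mean-field and LNA computations are effectively
instantaneous and always use full-scale copy numbers.

## What the simulator does and does not emulate

The generator reproduces: receptor cooperativity with methylation- and
ligand-dependent activity; slow, measured-time-scale enzyme exchange
between bulk and cluster; assistance neighborhoods and brachiation with
their processive degradations (M2/M3); activity-dependent binding; the
CheB phosphorylation feedback; and copy-number scales from published
estimates. It does not include: receptor types other than Tar, the
CheA/CheY/CheZ phosphorelay and motor (the output is receptor-kinase
activity, not behavior), explicit cytoplasmic diffusion (the bulk is
well-mixed), receptor exchange with a membrane pool, multiple disjoint
clusters, or 3-D membrane geometry. Passing tests therefore support claims
about the modeled reaction network on an idealized lattice, not about
absolute noise magnitudes in any particular real cell.

## Numerical choices and degenerate inputs

* Activity is clamped to $(10^{-12}, 1 - 10^{-12})$ in the analytical
  models to keep rates finite; for $|F| \gtrsim 37$ kT the MWC activity
  saturates at floating-point 0/1, so strict-monotonicity guarantees apply
  on the representable range.
* Steady states with no interior balance (an enzyme absent, or $m_0$
  outside $[0, 8N]$) are flagged `interior = FALSE` — the "nonfunctional
  cell" regimes — rather than silently extrapolated.
* The Lyapunov solver refuses non-Hurwitz drift and verifies its residual
  to $10^{-10}$; the variance decomposition verifies additivity to
  $10^{-10}$.
* SSA target selection uses rejection sampling (uniform over free tethers;
  activity-weighted over free modification sites) with an exact
  cumulative-scan fallback, so selection remains exact at any occupancy.
* Engine audits (conservation, site exclusivity, neighborhood membership
  of doubly bound enzymes, pool counters) run at initialization and
  completion of every run and hard-fail on violation.

## Known limitations

* The mean-field model and the lattice simulator agree qualitatively
  (orderings, precise adaptation, ultrasensitivity to the localized
  ratio) but not quantitatively at matched copy numbers; the gap *is* the
  finite-distributivity physics, and no correction for it is implemented
  (the detailed finite-brachiation analytical treatment is out of scope).
* With the CheB-P feedback retained, the high-affinity B2 variant steepens
  the activity-vs-CheR curve by about twofold over B1 rather than becoming
  fully switch-like; the feedback contributes a first-order term that
  bounds zero-order ultrasensitivity.
* Ramp-response fitting assumes a single-exponential approach to the
  steady ramp activity; for very fast ramps the active window is short and
  the plateau is an extrapolation of the fit.
* The population protocol discretizes expression multipliers to whole
  hexagonal lattice units.
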