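# chemadapt

Adaptation kinetics on clustered bacterial chemoreceptor lattices: an
exact stochastic simulator of CheR/CheB-P methylation dynamics on a
hexagonal receptor lattice, together with the matching mean-field
analytical model with enzyme localization and its linear-noise analysis.

## The science

In *E. coli* chemotaxis, receptor dimers pack into a dense hexagonal
lattice. Adaptation is carried by two scarce cytoplasmic enzymes — CheR
methylates inactive receptors, CheB-P demethylates active ones — which
must localize to the cluster (mostly via a high-affinity tether site)
before they can act. A tethered enzyme reaches the modification sites of
its own dimer and its six nearest neighbors (the *assistance
neighborhood*, 7 dimers), and can walk hand-over-hand across the lattice
(*brachiation*). Receptor cooperativity follows an equilibrium MWC model
per 6-dimer complex:

    F(m, L) = eps_m (m_half − m) + N log[(1 + L/K_off)/(1 + L/K_on)],
    a = 1 / (1 + exp F)

The package implements:

* **`simulate_lattice()`** — exact Gillespie simulation of the full rule
  set (tether/modification-site binding, brachiation, activity-weighted
  kinetics, CheB phosphorylation feedback) with variants **M1**
  (reference), **M2** (no assistance neighborhoods or brachiation), **M3**
  (inefficient brachiation), and the well-mixed baseline **B1** (no
  localization at all; **B2** = tenfold affinity).
* **`mf_steady_state()` / `mf_noise()`** — the mean-field model with
  localization: precise adaptation by construction, Goldbeter–Koshland
  reduction with effective constants `K̃ = K(1 + k_t−/k_t+)·(feedback)`
  (`mf_effective_constants()`), and activity fluctuations from the
  Lyapunov equation of the linearized system, decomposed exactly into
  localized-CheR, localized-CheB-P and intrinsic-methylation parts.
* **Experiment drivers** — ligand steps and exponential ramps
  (`adaptation_precision()`, `ramp_response()`), CheR scans
  (`param_scan()` over SSA / mean-field / LNA engines), log-normal
  populations with the CheR/CheB/receptor ratio preserved
  (`population_run()`), and the enzyme processivity metric
  (`processivity_rate()`: unique dimers visited per localized
  enzyme-second).

The central result the models expose: distributive methylation (assistance
neighborhoods + brachiation) is what makes adaptation precise, and the
same localization machinery makes the adapted state noisy — saturated
localized enzymes render activity ultrasensitive to the *localized*
CheR/CheB-P ratio, amplifying slow fluctuations in localized enzyme
numbers — while slow tether exchange keeps the mean activity robust to
*total* expression levels.

## Worked example

```r
library(chemadapt)

lat <- build_lattice(8, 8)          # reduced lattice, enzyme density preserved
lat
#> Receptor lattice: 1152 dimers, 192 MWC complexes (8 x 8 units)
#>   interior dimers (6 neighbors): 1012; boundary dimers: 140

eq <- equilibrate_lattice(lat, rate_set(), copy_numbers(lat),
                          burn_in = 500, duration = 600, seed = 1)
summary(eq$trace)
#> Variant M1 on 1152 dimers, 600 s
#>   a0 = 0.5058, sigma_aa = 0.00216, sigma_a/a0 = 9.19%
#>   mean localized CheR 6.5, CheB-P 17.6
```

The adapted activity sits in the typical 0.3–0.5 band and fluctuates with
a standard deviation of ~9% of the mean — the large spontaneous noise that
enzyme localization produces. The same cell's processivity:

```r
processivity_rate(eq$trace)
#> Unique dimers visited per localized enzyme-second:
#>   cheR  3.613  (14101 visits over 3903 s localized)
#>   cheB  1.842  (19505 visits over 1.059e+04 s localized)
```

Localized enzymes sample several receptors per second — distributive
kinetics. Under M2 (no brachiation) these rates drop roughly fivefold and
each residence touches exactly one dimer. The analytical counterpart:

```r
mf_noise(meanfield_params())
#> Activity noise: a0 = 0.2086, sigma_aa = 0.0004679, sigma_a/a0 = 10.37%
#>   decomposition: m = 4.86e-05, r = 0.000203, b = 0.000216
```

The decomposition shows fluctuations in localized CheR (`r`) and CheB-P
(`b`) dominating the intrinsic methylation noise (`m`) about ninefold —
the mechanistic reading of where the noise comes from. The B1 baseline
(`mf_noise(b1_params())`) stays near 2%.

A YAML-driven command line sits in `inst/cli/chemadapt.R`
(`simulate | meanfield | scan | noise`); see `?read_run_config`.

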