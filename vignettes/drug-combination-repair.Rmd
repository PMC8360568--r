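---
title: "Repairing mutant action potentials with optimal drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing mutant action potentials with optimal drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A gain-of-function mutation in an ion channel can reshape the cardiac action
potential (AP) enough to be life-threatening. The hERG N588K mutation
(short QT syndrome type 1, SQT1) shifts the voltage dependence of I_Kr
inactivation towards positive potentials, leaving far more channels
conducting during the plateau; the AP shortens, the QT interval shrinks,
and the calcium transient — and with it contraction — is depressed.

`aprepair` implements a computational strategy for *repairing* such a
phenotype with combinations of existing, characterised drugs: find dose
vectors for a small drug library such that the mutant's AP and calcium
transient biomarkers move as close as possible to their wild-type values.

## The drug model

Each drug `k` acts on each current `i` through a Hill-type (EC50/IC50)
relationship. The relative change of a current at dose `D` (in uM) is

    eta(D) = (eps * D)^H / ((eps * D)^H + 1) * E,     eps = 1 / EC50

so `eta(0) = 0`, `eta(EC50) = E/2`, `eta(Inf) = E`. `E = -1` is a complete
block; `E > 0` an agonist (there is a hard lower bound at -1 but no upper
bound). Several drugs combine multiplicatively per current,

    F_i(D) = prod_k (1 + eta_ik(D_k)),

which assumes strictly independent, non-interactive binding: if drug A
leaves a fraction `mu_A` of channels open and drug B a fraction `mu_B`,
applying both leaves `mu_A * mu_B`. State-dependent (Markov) binding and
competitive interactions are deliberately out of scope. `(eps*D)^H` is
computed as `exp(H * log(eps*D))` with an exact zero branch at `D = 0`,
since the library contains non-integer Hill coefficients.

The shipped library (`default_drug_library()`) contains nine drugs with
EC50, `H` and `E` per current, collected from published measurements: the
I_Kr entries were characterised on the SQT1 mutant channel, the I_CaL,
I_Na, I_NaL and I_f entries on wild-type channels. Empty drug/current
combinations are treated as *no effect* (factor 1), which is what the
published combination tables imply.

## The cell model and the rho * J split

Every membrane current is factored as `I_i = rho_i * J_i`, where `rho_i`
collects channel density (channels per membrane area over specific
capacitance) and `J_i = g0 * o * (v - E)` is the single-channel flux. The
package's central structural assumption is the orthogonality of this
split:

* maturation (hiPSC-CM to adult) and species translation (rabbit to human)
  change **only** `rho_i`;
* the mutation and drug block/agonism change **only** `J_i`.

Because drugs act inside `J`, a drug factor estimated in one cell type is
valid in any other — this is what makes dose predictions transferable
between hiPSC-CM, rabbit and adult human parameterisations, and it is
enforced and tested as a package invariant (`model_factors()` is
independent of cell type; current ratios across cell types are independent
of mutation).

The N588K mutation is a modification of the I_Kr inactivation-gate steady
state only:

    WT:     xKr2_inf(v) = 1 / (1 + exp((v + 70) / 20.9))
    N588K:  xKr2_inf(v) = 1 / (1 + exp((v + 70 - 62) / (20.9 * 1.85)))

a +62 mV midpoint shift with 1.85-fold slope-factor scaling (`xkr2_inf()`).

### The surrogate parameter set

The base cell model used in the original analyses resides in prior
published work and is not reproducible from in-package information, so the
package ships a fully documented *synthetic surrogate* ventricular
parameter set (`extdata/surrogate_model.yaml`): twelve currents (I_Na,
I_NaL, I_CaL, I_Kr, I_Ks, I_K1, I_to, I_f, I_NaCa, I_NaK, I_bCl, I_bCa)
with Hodgkin–Huxley gates, fixed intracellular Na+/K+, and a
two-compartment (cytosol/SR) calcium subsystem with instantaneous
buffering. Conductances were chosen so the adult wild type paces stably at
1 Hz with a realistic resting potential (about -82 mV), upstroke velocity
(about 260 mV/ms) and APD90 (about 250 ms), and so the surrogate
reproduces the qualitative SQT1 contrasts: the mutant beat is markedly
shorter and its calcium transient smaller, in all three cell-type
profiles. The hiPSC-CM profile lowers I_K1, I_Na and I_to densities and
raises I_f, giving the depolarised resting potential and slow upstroke
typical of immature myocytes.

What the surrogate does **not** emulate: the exact AP morphology and
biomarker magnitudes of any published human model, rate dependence and
restitution, alternans, intracellular ion accumulation, or
population-level density variability. Consequently all *numeric*
acceptance of this package is restricted to closed-form drug arithmetic
against published dose tables; AP-level claims are checked as qualitative
properties (shorter mutant APD90, depressed CaA, cost improvement by
combinations) that are robust to the surrogate's particulars. Any
externally published parameter set following the documented YAML schema
(conductances, density profiles, reversal potentials, calcium handling,
initial state) can be dropped in; gate kinetics are fixed functional
forms.

## Pacing, integration and biomarkers

The pacing protocol is deliberately conventional, since protocols differ
between laboratories: cycle length 1000 ms, rectangular 1 ms stimulus of
50 A/F (about 1.5x the surrogate's diastolic threshold, which sits between
30 and 35 A/F), up to 100 conditioning beats with an early stop when every
state variable changes by less than 0.1% (relative to its resting
magnitude) between consecutive beat ends.

Integration uses `deSolve::lsoda` (adaptive, stiff-switching) with a
compiled right-hand side, relative tolerance 1e-6 and per-state absolute
tolerances scaled to resting magnitudes (1e-4 mV for voltage, 1e-9 mM for
cytosolic calcium). The analysed beat is returned on a uniform 0.05 ms
grid. Tightening `rtol` tenfold moves APD90 by well under 0.5 ms (tested).

Biomarker conventions (`compute_biomarkers()`):

* RMP and CaR are the values at stimulus onset; APA and CaA are peak minus
  rest.
* Maximal upstroke velocities use central differences on the uniform grid,
  with the search started at stimulus end so the stimulus artifact cannot
  masquerade as the upstroke.
* APDp runs from the instant of maximal upstroke velocity to the first
  subsequent downward crossing of `peak - (p/100) * APA`, linearly
  interpolated between grid points. The start convention (dvdt-max) is a
  package decision: it is the dominant convention and is self-consistent
  across drug runs.
* Thresholds are referenced to the beat's own amplitude, not to fixed
  voltages.
* Calcium durations default to the same decay-from-peak convention
  (`"decay"`); a width-at-percent-of-amplitude reading (`"width"`) is also
  implemented because figure captions of this kind are ambiguous between
  the two.
* A threshold never re-crossed within the beat yields the beat-end value
  flagged as censored rather than an error, so the optimizer can still
  rank such doses (an AP that fails to repolarise is simply very costly).

The synthetic-trace generator (`synth_trace()`) produces beats with
half-cosine upstrokes (unique, analytically known maximal-slope instant)
and linear or exponential decays, returning the closed-form biomarker
panel alongside; the extractor is required to recover durations within two
grid steps and amplitudes to 1e-6 relative.

## Cost function and optimizer

The repair cost of a dose vector `D` is

    C(D) = sum_j w_j * |R_j^M(D) - R_j^W| / |R_j^W|

over the 18-biomarker panel (RMP, APA, dvdt_max, APD10..APD90, CaR, CaA,
dcdt_max, CaD30/50/80), with weights 1 except APD80, APD90 and dvdt_max at
5 — late repolarization is the phenotype being repaired, and the upstroke
guards against overdosing sodium-channel blockers. Drug evaluations start
from the paced steady state of the *untreated mutant* (the clinical
framing: a drug applied to an established phenotype) and pace 6–8 further
conditioning beats; the zero-dose evaluation is the untreated baseline
itself.

The search is deterministic and derivative-free throughout; it needs no
random seed.

* **Single drug**: a fixed 5-point lattice on `[0, bound]` is screened and
  the two best points refined by bounded golden-section search; near-ties
  (within 1e-4 cost) resolve towards the lower dose.
* **Combinations**: incremental continuation. The best `n`-drug solution
  seeds each candidate `(n+1)`-drug problem with the new drug at dose
  zero; the local search is Nelder–Mead in unit coordinates (dose/bound),
  clamped to the box with a quadratic excursion penalty, stopping at a
  1e-4 relative cost spread. Because the continuation start is itself
  evaluated, the reported cost sequence is non-increasing in `n` by
  construction. For two-drug problems a 5x5 start lattice is screened
  first and the three best points refined — screening the full lattice but
  refining only the leaders keeps determinism while avoiding a sevenfold
  ODE bill for starts that cannot win.
* **Pruning**: after each candidate search, any dose whose removal changes
  the cost by at most 1e-4 (without breaking monotonicity) is zeroed —
  the concrete form of the lower-dose preference.
* **Caching**: evaluations are memoised on dose vectors rounded to six
  significant digits, which collapses the repeated lattice corners and
  clamped simplex excursions.

Dose caps (`dose_bounds()`): the default `saturation-cap` limits each drug
to the dose at which its most potent target reaches 95% of its maximum
effect (`EC50 * 19^(1/H)`, minimised over targets) — beyond that point the
dose–response is flat and higher doses only add off-target load. The
restricted modes `min-ec50` and `half-min-ec50` implement the low-dose
searches (`D <= min(EC50)` and `D <= min(EC50)/2`) under which more drugs
are needed but each stays far from saturation.

## Problem sizes and runtime

The package's demonstration analyses (tests and the end-to-end pipeline)
use the surrogate model at a 0.1 ms analysis grid with 40 conditioning
beats for baselines and 6 per optimizer evaluation; a full nine-drug
incremental search to five drugs costs roughly 3,500 ODE evaluations and
about two minutes on one core. The finer 0.05 ms default grid is used for
reported traces and biomarker tables.

## Known limitations

* The multiplicative combination rule is an assumption (independent
  binding); synergistic or competitive interactions are not modelled.
* Pore-block scaling of I_Kr cannot exactly undo the N588K change of
  voltage dependence — a blocked mutant current is a scaled mutant
  current, not a wild-type one. Repair is therefore judged on the AP and
  calcium waveform, not on the current itself.
* The surrogate's biomarker magnitudes are not those of any published
  human myocyte model; quantitative dose predictions require dropping in
  a validated parameter set.
* Published EC50 values vary considerably between laboratories; the
  shipped library inherits that uncertainty.
* Optimization is local with deterministic multistart; there is no global
  optimality guarantee, and robustness across ion-channel-density
  populations is a config-level extension, not implemented.
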