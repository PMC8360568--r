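# aprepair

Computational repair of mutant cardiac action potentials with optimal
combinations of existing drugs.

Some ion-channel mutations reshape the ventricular action potential (AP)
dangerously. The hERG N588K mutation (short QT syndrome type 1) shifts
I_Kr inactivation by +62 mV, leaving the repolarising current far too
large: the AP shortens and the calcium transient — and contraction — is
depressed. `aprepair` searches a library of characterised drugs for dose
combinations that move the mutant's AP and Ca²⁺ biomarkers back to their
wild-type values.

The package is aimed at cardiac electrophysiology modellers and
systems-pharmacology researchers who want to rank candidate drug
combinations in silico before committing to experiments.

## The model

Each drug `k` scales each ion current `i` through a Hill (EC50/IC50)
relationship, and drugs combine multiplicatively:

```
eta_ik(D) = (eps_ik D)^H_ik / ((eps_ik D)^H_ik + 1) * E_ik,   eps = 1/EC50
F_i(D)    = prod_k (1 + eta_ik(D_k))          # per-current scale factor
dv/dt     = - sum_i F_i(D) * I_i
```

`E = -1` is a complete block; `E > 0` an agonist. Every current is split
as `I_i = rho_i * J_i`: cell type (hiPSC-CM, rabbit, adult human) changes
only the channel density `rho_i`, while mutation and drugs act only on the
flux `J_i` — so drug parameters measured in one cell type transfer to the
others. Dose vectors are scored by a weighted biomarker cost

```
C(D) = sum_j w_j |R_j^M(D) - R_j^W| / |R_j^W|
```

over 18 AP and Ca²⁺ biomarkers (weights 1, except APD80, APD90 and
dvdt_max at 5), and minimised by a deterministic incremental search: the
best n-drug solution seeds every candidate (n+1)-drug search with the new
drug at dose zero, so cost is non-increasing in n.

The package ships a nine-drug library (EC50, Hill coefficient, maximum
effect per current, with the I_Kr entries measured on the SQT1 mutant
channel) and a synthetic surrogate ventricular AP model (documented YAML
schema; published parameter sets can be dropped in).

## Worked example

```r
library(aprepair)

lib    <- default_drug_library()
mutant <- build_ap_model(cell_type = "adult-human", mutation = "N588K")
proto  <- pacing_protocol(n_prebeats = 40, dt_output = 0.1)

ctx <- repair_context(mutant, lib, protocol = proto, eval_prebeats = 6)
round(ctx$wt_biomarkers[c("APD50", "APD90", "CaA")], 1)
#> APD50 APD90   CaA
#> 206.6 253.1   1.2
round(ctx$mutant_biomarkers[c("APD50", "APD90", "CaA")], 1)
#> APD50 APD90   CaA
#> 121.2 164.4   0.9
round(ctx$untreated_cost, 2)
#> [1] 6.65

inc <- optimize_incremental(lib, dose_bounds(lib, "saturation-cap"),
                            ctx, max_drugs = 2)
inc[[2]]
#> <optimization_result> cost = 1.03294
#>   disopyramide   132.384 uM
#>   veratridine    1.85511 uM
```

The untreated mutant beat is 35% shorter than wild type (APD50 121 vs
207 ms) with a depressed Ca²⁺ transient, at cost 6.65. The optimizer's
best pair — the I_Kr blocker disopyramide plus the late-sodium agonist
veratridine, the classic block-and-compensate pairing — cuts the cost to
1.03 and restores APD50/APD90 to within a millisecond of wild type:

```r
treated <- attr(ap_cost(ctx, inc[[2]]$doses), "biomarkers")
round(treated[c("APD50", "APD90", "CaA")], 1)
#> APD50 APD90   CaA
#> 206.3 252.9   1.1

percent_change_table(lib, inc[[2]]$doses,
                     currents = c("I_Kr", "I_CaL", "I_Na", "I_NaL", "I_f"))
#>  current percent_change
#>     I_Kr         -78.2%
#>    I_CaL          -8.8%
#>     I_Na         -13.5%
#>    I_NaL        +171.0%
#>      I_f          +0.0%
```

The end-to-end pipeline (baselines, optional pairwise scan, incremental
search, trace/biomarker/dose reports and a JSON summary) is
`run_repair(run_config(...))`; a thin command-line driver with
`simulate`, `biomarkers`, `percent-change`, `scan-pairs`, `optimize` and
`repair` subcommands is installed at `inst/cli/aprepair.R`.

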