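# Surrogate ventricular action-potential model (synthetic parameter set).
#
# This is NOT a published cell model: it is a compact Hodgkin-Huxley style
# ventricular surrogate authored for this package, with a two-compartment
# calcium subsystem and fixed intracellular Na+/K+. Each current is stored
# as a channel-density scaling rho (per cell type) and single-channel flux
# parameters (g0, shared reversal potentials), so that maturation/species
# translation only rescales rho while mutation and drug effects only touch
# the flux. Conductances are in mS/uF (giving currents in A/F), potentials
# in mV, concentrations in mM, time in ms.
#
# Schema (aprepair-ap-model-1):
#   currents.<id>.g0            single-channel conductance scale (mS/uF)
#   currents.<id>.rho.<cell>    density scaling per cell type (>= 0)
#   constants                   reversal potentials and exchanger/pump shape
#   calcium                     SR uptake/release/leak and buffering
#   initial_state               resting state used to start pacing
schema: aprepair-ap-model-1
name: surrogate-ventricular-1
calcium_state_unit: mM
currents:
  I_Na:   {g0: 14.0,    rho: {adult-human: 1.0, rabbit: 1.0,  hiPSC-CM: 0.40}}
  I_NaL:  {g0: 0.012,   rho: {adult-human: 1.0, rabbit: 0.8,  hiPSC-CM: 1.0}}
  I_CaL:  {g0: 0.15,    rho: {adult-human: 1.0, rabbit: 1.1,  hiPSC-CM: 0.80}}
  I_Kr:   {g0: 0.060,    rho: {adult-human: 1.0, rabbit: 1.25, hiPSC-CM: 0.90}}
  I_Ks:   {g0: 0.32,    rho: {adult-human: 1.0, rabbit: 0.5,  hiPSC-CM: 0.50}}
  I_K1:   {g0: 0.50,    rho: {adult-human: 1.0, rabbit: 1.0,  hiPSC-CM: 0.25}}
  I_to:   {g0: 0.20,    rho: {adult-human: 1.0, rabbit: 0.8,  hiPSC-CM: 0.30}}
  I_f:    {g0: 0.06,    rho: {adult-human: 1.0, rabbit: 0.15, hiPSC-CM: 3.0}}
  I_NaCa: {g0: 900.0,   rho: {adult-human: 1.0, rabbit: 0.9,  hiPSC-CM: 1.3}}
  I_NaK:  {g0: 0.60,    rho: {adult-human: 1.0, rabbit: 1.0,  hiPSC-CM: 0.70}}
  I_bCl:  {g0: 0.003,   rho: {adult-human: 1.0, rabbit: 1.0,  hiPSC-CM: 1.0}}
  I_bCa:  {g0: 0.0005,  rho: {adult-human: 1.0, rabbit: 1.0,  hiPSC-CM: 1.0}}
constants:
  E_Na: 70.0
  E_K: -87.0
  E_CaL: 60.0
  E_f: -17.0
  E_Cl: -40.0
  naca_a: 6.56e-4     # (Nai/Nao)^3 * Cao, fixed Na gradients
  ksat: 0.2           # NCX low-voltage saturation
  kCa: 5.8e-5         # mM per (A/F * ms): membrane flux to cytosolic Ca
  cao: 1.8            # extracellular Ca2+ (mM)
  fca_k: 1.0e-3       # Ca-dependent I_CaL inactivation midpoint (mM)
calcium:
  Vmaxup: 4.25e-4     # SR uptake Vmax (mM/ms)
  Kup: 2.5e-4         # SR uptake Km (mM)
  krel: 0.010         # CICR release rate (1/ms, gated by d*f)
  kleak: 8.0e-5       # SR leak rate (1/ms)
  vc_vsr: 15.0        # cytosol/SR volume ratio
initial_state:
  v: -86.0
  m: 4.6e-4
  h: 0.93
  j: 0.93
  hL: 0.31
  d: 6.0e-6
  f: 1.0
  xr1: 4.0e-5
  xs: 1.5e-3
  s: 1.0
  "y": 0.47
  cai: 1.0e-4
  casr: 1.0
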