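# Default drug library: EC50 (uM), Hill coefficient and maximum effect per
# ion current, collected from published voltage-clamp and hiPSC-CM studies.
# I_Kr entries were measured on the SQT1 (hERG N588K) mutant channel; the
# other currents are wild type. emax = -1 is a full block at saturating
# dose; emax > 0 is an agonist. Absent current blocks mean "no effect".
schema: aprepair-drug-library-1
drugs:
  quinidine:
    I_Kr:  {ec50_uM: 8.14,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_CaL: {ec50_uM: 153,    hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_Na:  {ec50_uM: 77.7,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
  ivabradine:
    I_Kr:  {ec50_uM: 12.6,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_Na:  {ec50_uM: 86.3,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_f:   {ec50_uM: 42,     hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
  ajmaline:
    I_Kr:  {ec50_uM: 69.5,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_CaL: {ec50_uM: 46.6,   hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_Na:  {ec50_uM: 435,    hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
  mexiletine:
    I_Kr:  {ec50_uM: 281,    hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_CaL: {ec50_uM: 963,    hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
    I_Na:  {ec50_uM: 201,    hill: 1,    emax: -1,     source: "SQT1 hiPSC-CM estimate"}
  BAY K 8644:
    I_CaL: {ec50_uM: 0.05,   hill: 1.7,  emax: 1.8,    source: "literature agonist estimate"}
  veratridine:
    I_NaL: {ec50_uM: 0.426,  hill: 2,    emax: 1.8,    source: "literature agonist estimate"}
  disopyramide:
    I_Kr:  {ec50_uM: 15.77,  hill: 0.6,  emax: -1,     source: "SQT1 voltage-clamp dose-response"}
    I_CaL: {ec50_uM: 1036.7, hill: 1,    emax: -0.779, source: "patch-clamp drug screen"}
    I_Na:  {ec50_uM: 168.4,  hill: 1.09, emax: -0.311, source: "patch-clamp drug screen"}
  propafenone:
    I_Kr:  {ec50_uM: 0.95,   hill: 0.7,  emax: -1,     source: "SQT1 voltage-clamp dose-response"}
    I_CaL: {ec50_uM: 1.55,   hill: 0.9,  emax: -1,     source: "patch-clamp drug screen"}
    I_Na:  {ec50_uM: 3.886,  hill: 0.9,  emax: -1,     source: "patch-clamp drug screen"}
    I_NaL: {ec50_uM: 4.036,  hill: 0.9,  emax: -1,     source: "patch-clamp drug screen"}
  amiodarone:
    I_Kr:  {ec50_uM: 0.318,  hill: 0.5,  emax: -1,     source: "SQT1 voltage-clamp dose-response"}
    I_CaL: {ec50_uM: 1.28,   hill: 0.6,  emax: -1,     source: "patch-clamp drug screen"}
    I_Na:  {ec50_uM: 4.58,   hill: 0.7,  emax: -1,     source: "patch-clamp drug screen"}
    I_NaL: {ec50_uM: 9.42,   hill: 0.4,  emax: -1,     source: "patch-clamp drug screen"}
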