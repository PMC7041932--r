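# Reference parameterization of the hemiconcerted calmodulin model.
# Units: dissociation constants and concentrations in M, association rates
# in /M/s, first-order rates in /s, volume in L.
allosteric:
  LN: 299            # [T]/[R] of the N lobe at zero calcium
  LC: 195865
  cN: 0.01           # K_R/K_T per lobe (calcium favours the open state)
  cC: 5.0e-5
  KNT: 9.38e-5       # per-site calcium Kd of the closed lobe
  KCT: 9.38e-5
  kon_N: 1.22e+10    # per-site calcium association (N lobe 100x faster)
  kon_C: 1.22e+8
  k0_N: 316227       # T->R base transition rate at zero calcium
  k0_C: 316227
  e: 1               # Ng affinity ratio RT/TT (blind to the N lobe)
partners:
  kon_CaMKII_RR: 2.87e+6
  koff_CaMKII_RR: 1.1
  kon_CaMKIIp_RR: 3.85e+7
  koff_CaMKIIp_RR: 8.7e-5
  kon_CaN_RR: 2.3e+7
  Kd_CaN_RR: 3.26e-9
  kon_Ng: 1.0e+14
  Kd_Ng_TT: 1.2e-6
  kon_CaN_Ca: 2.0e+7
  koff_CaN_Ca: [0.0092, 0.0312, 0.352, 0.9]
  k_autop: 6.3
  kcat_CaN_CaMKIIp: 0.8
  Km_CaN_CaMKIIp: 2.0e-5
  kcat_CaMKII_GluR1: 2
  kcat_CaN_GluR1: 0.5
model:
  CaM: 4.0e-5
  CaMKII: 8.0e-5
  CaN: 8.0e-6
  Ng: 4.0e-5
  Ca: 8.0e-8
  leak: 3.85e-6
  pump_Vmax: 1.0e-4
  pump_Km: 2.0e-6
  volume: 1.0e-15
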