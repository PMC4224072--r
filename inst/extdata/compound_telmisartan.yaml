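# Telmisartan, human parameterization.
# Large distribution volume, modest hepatic uptake, efficient hepatic
# elimination (glucuronidation lumped into parent biliary clearance: the
# glucuronide neither inhibits BSEP nor is tracked in plasma).
# BSEP Ki 16 uM approximated from the reported IC50 (mode undetermined;
# scenarios run both modes).
name: telmisartan
molecular_weight_g_per_mol: 514.6
ka_per_h: 1.0
f_abs: 0.45
uptake_vmax_umol_per_h_per_kg075: 5
uptake_km_uM: 5
passive_cl_L_per_h: 0.5
biliary_cl_mL_per_h_per_kg075: 250
renal_cl_L_per_h: 0
v_central_L_per_kg: 1.5
v_peripheral_L_per_kg: 4.0
q_peripheral_L_per_h: 20
inhibitions:
  - {transporter: BSEP, ki_uM: 16, mode: noncompetitive}
metabolites: []
default_regimen: {amount_mg: 50, interval_h: 24, n_doses: 30, route: oral}
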