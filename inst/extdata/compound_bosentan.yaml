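# Bosentan, human parameterization.
# PK targets: Cmax ~3 uM and apparent half-life ~5 h after 500 mg oral,
# active hepatic uptake (OATP substrate), two metabolite pathways (the
# minor metabolite also inhibits BSEP), autoinduction of uptake and
# metabolism on repeated dosing.
name: bosentan
molecular_weight_g_per_mol: 551.6
ka_per_h: 0.7
f_abs: 0.5
uptake_vmax_umol_per_h_per_kg075: 36
uptake_km_uM: 15
passive_cl_L_per_h: 1.0
biliary_cl_mL_per_h_per_kg075: 100
renal_cl_L_per_h: 0
v_central_L_per_kg: 0.25
v_peripheral_L_per_kg: 0.15
q_peripheral_L_per_h: 5
induction:
  targets: [uptake_vmax, metabolism_vmax]
  fold_max: 2.0
  k_ind_per_h: 0.01
inhibitions:
  - {transporter: BSEP, ki_uM: 12, mode: noncompetitive}
  - {transporter: NTCP, ki_uM: 18, mode: competitive}
metabolites:
  - product_name: bosentan_major_metabolite
    vmax_formation_umol_per_h: 100
    km_formation_uM: 20
    product_biliary_cl_mL_per_h_per_kg075: 60
    product_passive_cl_L_per_h: 1.0
    product_inhibitions: []
  - product_name: bosentan_minor_metabolite
    vmax_formation_umol_per_h: 40
    km_formation_uM: 20
    product_biliary_cl_mL_per_h_per_kg075: 100
    product_passive_cl_L_per_h: 1.0
    product_inhibitions:
      - {transporter: BSEP, ki_uM: 8.5, mode: noncompetitive}
default_regimen: {amount_mg: 500, interval_h: 12, n_doses: 60, route: oral}
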