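# Physicochemical records of the five study chemicals: experimentally
# determined saturated water solubility S_W (mol/L), log K_OW, the apparent
# saturated n-octanol solubility S_O (mol/L) as reported in the literature
# compilation, molar masses (g/mol) and experimental log K_OA determinations.
chemicals:
  - id: PCB-4
    name: "2,2'-dichlorobiphenyl"
    s_w: 1.91e-6
    log_kow: 4.90
    s_o_reported: 1.51e-1
    molar_mass: 223.10
    n_aromatic_rings: 2
    exp_log_koa: [7.18]
  - id: Phenanthrene
    name: "phenanthrene"
    s_w: 6.03e-6
    log_kow: 4.57
    s_o_reported: 2.24e-1
    molar_mass: 178.23
    n_aromatic_rings: 3
    exp_log_koa: [7.45, 7.57, 7.88, 7.68]
  - id: PBDE-28
    name: "2,4,4'-tribromodiphenyl ether"
    s_w: 1.72e-7
    log_kow: 5.94
    s_o_reported: 1.50e-1
    molar_mass: 406.90
    n_aromatic_rings: 2
    exp_log_koa: [9.50]
  - id: PCN-5
    name: "1,8-dichloronaphthalene"
    s_w: 1.60e-6
    log_kow: 4.78
    s_o_reported: 9.67e-2
    molar_mass: 197.06
    n_aromatic_rings: 2
    exp_log_koa: [6.93]
  - id: PCDD-1
    name: "1-chlorodibenzo-p-dioxin"
    s_w: 1.91e-6
    log_kow: 5.05
    s_o_reported: 2.14e-1
    molar_mass: 218.64
    n_aromatic_rings: 2
    exp_log_koa: [7.86]
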