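# Literature reference values the fixture report compares against. These are
# comparison metadata, not computation inputs: every number the pipeline
# reports is recomputed from the chemicals registry and planted conformations.
#
# Cluster counts (dimers/trimers) are the aggregate end states observed in the
# source simulations; the planted-fixture generator realizes them and the
# census pipeline must recover the corresponding percentages.

# Saturated boxes of 1000 n-octanol molecules.
saturated_boxes:
  PCB-4:        {n_solute: 24, n_octanol: 1000}
  Phenanthrene: {n_solute: 35, n_octanol: 1000}
  PBDE-28:      {n_solute: 24, n_octanol: 1000}
  PCN-5:        {n_solute: 15, n_octanol: 1000}
  PCDD-1:       {n_solute: 34, n_octanol: 1000}

# Reported apparent saturated n-octanol solubilities, mol/L (see also the
# chemicals registry); PCN-5's reported value differs from s_w * 10^log_kow
# in the third significant figure.
s_o_reported:
  PCB-4: 1.51e-1
  Phenanthrene: 2.24e-1
  PBDE-28: 1.50e-1
  PCN-5: 9.67e-2
  PCDD-1: 2.14e-1

# Representative experimental log K_OA (mean of determinations, 2 decimals).
average_log_koa:
  PCB-4: 7.18
  Phenanthrene: 7.65
  PBDE-28: 9.50
  PCN-5: 6.93
  PCDD-1: 7.86

# Aggregate end state of the saturated boxes at the 50 ps checkpoint:
# cluster counts and the percentages the census must reproduce.
saturated_50ps:
  PCB-4:        {dimers: 3, trimers: 0, monomer: 75.0, dimer: 25.0, trimer: 0.0}
  Phenanthrene: {dimers: 5, trimers: 0, monomer: 71.4, dimer: 28.6, trimer: 0.0}
  PBDE-28:      {dimers: 4, trimers: 0, monomer: 66.7, dimer: 33.3, trimer: 0.0}
  PCN-5:        {dimers: 3, trimers: 0, monomer: 60.0, dimer: 40.0, trimer: 0.0}
  PCDD-1:       {dimers: 7, trimers: 1, monomer: 50.0, dimer: 41.2, trimer: 8.8}

# Equilibrium-state census grid (checkpoints in ns). Two cells deviate from
# the constant pattern in the source data (transient excursions): PCN-5 at
# 20 ns (73.3/26.7) and PCDD-1 at 10 ns (55.9/35.3). A dynamic-equilibrium
# trajectory with conserved cluster counts reproduces the constant pattern,
# so those two cells are excluded from pass/fail comparison.
equilibrium_grid:
  checkpoints: [0, 10, 20, 30, 40, 50]
  excursions:
    - {chemical: PCN-5, checkpoint: 20, monomer: 73.3, dimer: 26.7}
    - {chemical: PCDD-1, checkpoint: 10, monomer: 55.9, dimer: 35.3}

# Equal-concentration condition: 9.67e-2 mol/L, 61 solutes in 4000 n-octanol.
# PCN-5's printed percentages (60.0/40.0) correspond to 12 dimers among 60
# molecules, not 61 (12 dimers / 61 molecules gives 39.3% dimer); that row is
# flagged and excluded from exact comparison.
equal_concentration:
  concentration: 9.67e-2
  n_solute: 61
  n_octanol: 4000
  rows:
    PCB-4:        {dimers: 4,  monomer: 86.9, dimer: 13.1, exact: true}
    Phenanthrene: {dimers: 4,  monomer: 86.9, dimer: 13.1, exact: true}
    PBDE-28:      {dimers: 8,  monomer: 73.8, dimer: 26.2, exact: true}
    PCN-5:        {dimers: 12, monomer: 60.0, dimer: 40.0, exact: false}
    PCDD-1:       {dimers: 6,  monomer: 80.3, dimer: 19.7, exact: true}

# Fully-monomeric threshold concentrations: the stated fraction of the
# saturation concentration at which no dimers or trimers remain, mol/L
# (3-decimal display rounding).
monomeric_thresholds:
  PCB-4:        {divisor: 4,  concentration: 0.038}
  Phenanthrene: {divisor: 16, concentration: 0.014}
  PBDE-28:      {divisor: 8,  concentration: 0.019}
  PCN-5:        {divisor: 4,  concentration: 0.024}
  PCDD-1:       {divisor: 32, concentration: 0.007}

# Reported aggregation-corrected log K_OA estimates at the equal-concentration
# condition. The per-species solvation free energies behind them are not
# public, so these are reference metadata only and are never recomputed.
estimated_log_koa_reference:
  PCB-4: 7.24
  Phenanthrene: 7.17
  PBDE-28: 9.19
  PCN-5: 6.85
  PCDD-1: 5.72

# Per-pair aromatic stacking interaction energies, kcal/mol, used only to
# order the well depths of the Monte Carlo toy model.
stacking_energies:
  PCDD-1: -11.54
  PCN-5: -11.10
  PBDE-28: -10.98
  Phenanthrene: -10.37
  PCB-4: -9.77
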