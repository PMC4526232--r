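# Demo run: synthetic C2 elastic-network dimer in three liganded states
# (apo, one ligand, two ligands), nine replicas per state.
seed: 42
temperature_K: 300
output: dynallo_demo
model:
  n_res_per_protomer: 12
  nodes_per_residue: 4
  contact_cutoff_nm: 1.2
  k_default: 500          # kJ/mol/nm^2
  pocket_residues_A: [10, 11, 12]
  k_ligand: 1500          # kJ/mol/nm^2
sampling:
  n_replicas: 9
  n_frames: 400
  dt_ps: 20
analysis:
  cutoffs_pN: [2, 4]      # synthetic ligand perturbations are gentler than
                          # an all-atom force field; cutoffs scaled accordingly
  window_ps: 2000
  selection: mainchain
  mindist_pair: ["A:6", "B:6"]
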