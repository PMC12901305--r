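# Seated-female 10-DOF model: first-iteration published table values,
# best-effort parse.
#
# The source tables print the stiffness and damping columns as
# undelimited digit runs, so several stiffness values (k4 in
# particular) are ambiguous; the values below are a best-effort
# reading. k4 reads as 820.00 x10^3 N/m, which exceeds the stated
# 300000 N/m stiffness bound — it is kept as printed here and this
# file is for reference only. Use female_10dof_synthetic.yaml for
# analyses; validation rejects this file's k4 if constrained.
total_mass: 54
segments:
  - {name: head,        mass: 6.91}
  - {name: thorax,      mass: 16.19}
  - {name: abdomen,     mass: 10.80}
  - {name: pelvis,      mass: 10.25}
  - {name: upper_arm_L, mass: 2.87}
  - {name: forearm_L,   mass: 1.44}
  - {name: hand_L,      mass: 0.62}
  - {name: upper_arm_R, mass: 2.87}
  - {name: forearm_R,   mass: 1.44}
  - {name: hand_R,      mass: 0.62}
couplings:
  - {from: 1, to: 2,    k: 210300, c: 3210}
  - {from: 2, to: 3,    k: 160500, c: 2300}
  - {from: 3, to: 4,    k: 250000, c: 2650}
  - {from: 4, to: base, k: 820000, c: 1430}   # k4: ambiguous parse, exceeds bound
  - {from: 2, to: 5,    k: 260000, c: 2200}
  - {from: 5, to: 6,    k: 170000, c: 4000}
  - {from: 6, to: 7,    k: 280000, c: 2500}
  - {from: 2, to: 8,    k: 260000, c: 2200}
  - {from: 8, to: 9,    k: 170000, c: 4000}
  - {from: 9, to: 10,   k: 280000, c: 2500}
symmetry_pairs:
  - [5, 8]
  - [6, 9]
  - [7, 10]
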