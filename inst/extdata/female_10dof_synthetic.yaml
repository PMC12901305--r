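# Seated-female 10-DOF model: synthetic ground-truth fixture.
#
# Segment masses are the published optimized first-iteration values
# (they sum to 54.01 kg, consistent with the 54 kg total-mass
# constraint). Stiffness and damping are NOT fitted values: every
# coupling sits at the arithmetic midpoint of the physiological bounds
# (100, 300000) N/m and (500, 4000) N.s/m. This file is the
# illustrative "female-like" ground truth used for synthetic-target
# generation and parameter-recovery studies; it is synthetic, not an
# experimental parameter set.
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
  - {from: 1, to: 2,    k: 150050, c: 2250}   # head - thorax
  - {from: 2, to: 3,    k: 150050, c: 2250}   # thorax - abdomen
  - {from: 3, to: 4,    k: 150050, c: 2250}   # abdomen - pelvis
  - {from: 4, to: base, k: 150050, c: 2250}   # pelvis - seat
  - {from: 2, to: 5,    k: 150050, c: 2250}   # thorax - left upper arm
  - {from: 5, to: 6,    k: 150050, c: 2250}   # left upper arm - forearm
  - {from: 6, to: 7,    k: 150050, c: 2250}   # left forearm - hand
  - {from: 2, to: 8,    k: 150050, c: 2250}   # thorax - right upper arm
  - {from: 8, to: 9,    k: 150050, c: 2250}   # right upper arm - forearm
  - {from: 9, to: 10,   k: 150050, c: 2250}   # right forearm - hand
symmetry_pairs:
  - [5, 8]
  - [6, 9]
  - [7, 10]
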