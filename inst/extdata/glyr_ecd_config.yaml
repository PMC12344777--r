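# Default pocket definitions for the homopentameric glycine receptor ECD
# (alpha-1 author numbering). Seven principal-side and four
# complementary-side binding residues per interface, Loop C angle anchors,
# loop ranges, push-pull residue roles and conserved interfacial pairs.
principal_binding:
  resno: [115, 173, 174, 175, 218, 220, 223]
  resname: [PHE, GLU, SER, PHE, TYR, THR, PHE]
complementary_binding:
  resno: [79, 81, 133, 145]
  resname: [PHE, ARG, LEU, SER]
loopc_apex:
  resno: [219, 220]
  resname: [ASN, THR]
loopc_hinge:
  resno: [215, 224]
  resname: [THR, THR]
complementary_reference:
  resno: [58, 81]
  resname: [ASN, ARG]
loops:
  A: [111, 122]
  B: [173, 176]
  C: [215, 224]
  D: [77, 83]
  E: [133, 147]
  F: [185, 195]
  "2": [55, 70]
restrained_tail: [236, 240]
pushpull:
  loopB_resno: 174
  loopF_resno: 189
  loopE_resno: 145
conserved_pairs:
  principal_resno: [119, 49, 219, 220, 219]
  complementary_resno: [147, 96, 58, 135, 189]
  label: [GLU119-ARG147, LYS49-ASP96, ASN219-ASN58, THR220-ARG135, ASN219-LYS189]
occupancy: [true, true, true, true, true]
reverse_ring: false
water_resnames: [HOH, WAT, TIP3, SOL]
ligand_resnames: [LIG, GLZ]
ion_resnames: [NA, CL, SOD, CLA, K, POT]
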