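# Reference-set metadata: the 12 query families keyed by A. vinelandii DJ
# locus tags, plus the NifD (Avin_01390) residue numbering used for all
# ligand-environment profiling.  The bundled FASTA is a synthetic stand-in
# carrying the annotated residues at the annotated coordinates.
families:
  nifH: Avin_01380
  nifD: Avin_01390
  nifK: Avin_01400
  nifE: Avin_01450
  nifN: Avin_01460
  nifU: Avin_01620
  nifS: Avin_01630
  nifV: Avin_01640
  nifB: Avin_51010
  nifQ: Avin_51040
  anfG: Avin_48980
  vnfG: Avin_02600
minimum_gene_set: [nifH, nifD, nifK, nifE, nifN, nifB]
reference_numbering: nifD            # all alpha-subunit positions are NifD coordinates
ligand_positions:
  femoco_cys: 275
  femoco_his: 442
  gln: 191
  his: 195
  lys_homocitrate: 426
flank_positions: [276, 440, 444, 445]
p_cluster_alpha: [62, 88, 154]
# NifK numbering; only position 95 is part of the core annotation, the
# other two are package defaults and are configurable here.
p_cluster_beta_nifK: [70, 95, 153]
aromatic_residues: [F, W, Y]
acidic_residues: [D, E]
dual_numbering_notes:
  alphaC88: "corresponds to NifE C62 (written alpha-C88/alpha-C62)"
  alphaC154: "corresponds to NifE C124 (written alpha-C154/alpha-C124)"
  betaC95: "corresponds to NifN C44 (written beta-C95/beta-C44)"
dpor_references:
  chlB: AAT28195.1
  bchB: Q3APL0.1
  chlN: AAP99591.1
  bchN: Q3APK9.1
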