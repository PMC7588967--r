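# Substrate-channel patch definitions (ActKR crystal-structure numbering).
# The front- and back-patches form the two opposite entrances of the
# substrate channel; the active-site list is provided for channel-axis
# diagnostics only and is not used in classification.
patches:
  front:
    residues: ["A:38", "A:65", "A:93"]     # R38, R65, R93
  back:
    residues: ["A:149", "A:220", "A:260"]  # Q149, R220, N260
  active_site:
    residues: ["A:114", "A:144", "A:157", "A:161"]  # N114, S144, Y157, K161
threshold_A: 8.0
centroid_rule: all-heavy
reference_point: phosphorus
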