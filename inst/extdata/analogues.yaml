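# Palmerolide A-H analogue definitions.
#
# `assertions` use the assembled-structure feature vocabulary (positions on
# the numbered backbone; decorations on hydroxyls; Delta olefins named by
# their lower carbon).  `mechanisms` lists the diversity-mechanism classes a
# variant product may use to satisfy the assertions: trans_site (sites of
# action of the trans-acting tailoring enzymes: carbamoyl-transfer target
# swap with sulfation of the freed hydroxyl, hydroxylase site swap with
# olefin repositioning), starter (starter-unit promiscuity), core_geometry
# (core-module olefin-geometry difference), amide_hydrolysis (speculative
# post-assembly hydrolysis, starter-less clusters only).
- name: palmerolide_A
  mechanisms: []
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methylcrotonic_acid}
    - {type: tail_extension, value: 0}
    - {type: terminal_olefin, value: false}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: hydroxyl, position: 10}
    - {type: hydroxyl, position: 7, stereo: D}
    - {type: olefin, position: 14, geometry: trans}
    - {type: olefin, position: 21, geometry: trans}
    - {type: branch, position: 17}
    - {type: ring, to: 19}
- name: palmerolide_B
  mechanisms: [trans_site]
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methylcrotonic_acid}
    - {type: tail_extension, value: 0}
    - {type: terminal_olefin, value: false}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 7, decoration: carbamate}
    - {type: decoration, position: 11, decoration: sulfate}
    - {type: hydroxyl, position: 8}
    - {type: ring, to: 19}
- name: palmerolide_C
  mechanisms: [trans_site]
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methylcrotonic_acid}
    - {type: tail_extension, value: 0}
    - {type: terminal_olefin, value: false}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: hydroxyl, position: 8}
    - {type: ring, to: 19}
- name: palmerolide_D
  mechanisms: []
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methylcrotonic_acid}
    - {type: tail_extension, value: 1}
    - {type: terminal_olefin, value: false}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: hydroxyl, position: 10}
    - {type: ring, to: 19}
- name: palmerolide_E
  mechanisms: [amide_hydrolysis]
  speculative: true
  assertions:
    - {type: backbone_carbons, value: 22}
    - {type: starter, value: none}
    - {type: hydrolyzed, value: true}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: hydroxyl, position: 10}
    - {type: ring, to: 19}
- name: palmerolide_F
  mechanisms: [starter]
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methyl-3-butenoic_acid}
    - {type: tail_extension, value: 0}
    - {type: terminal_olefin, value: true}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: hydroxyl, position: 10}
    - {type: ring, to: 19}
- name: palmerolide_G
  mechanisms: [core_geometry]
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methylcrotonic_acid}
    - {type: tail_extension, value: 0}
    - {type: terminal_olefin, value: false}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 11, decoration: carbamate}
    - {type: olefin, position: 21, geometry: cis}
    - {type: ring, to: 19}
- name: palmerolide_H
  mechanisms: [trans_site, starter]
  assertions:
    - {type: backbone_carbons, value: 24}
    - {type: starter, value: 3-methyl-3-butenoic_acid}
    - {type: tail_extension, value: 1}
    - {type: terminal_olefin, value: true}
    - {type: hydrolyzed, value: false}
    - {type: decoration, position: 7, decoration: carbamate}
    - {type: decoration, position: 11, decoration: sulfate}
    - {type: hydroxyl, position: 8}
    - {type: ring, to: 19}
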