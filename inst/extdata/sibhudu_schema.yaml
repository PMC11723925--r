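- name: RMA
  scale: nominal
  levels:
  - Dolerite
  - Hornfels
  - Sandstone
  - Quartzite
  - Quartz
  codes:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
- name: CPE
  scale: continuous
- name: LEN
  scale: continuous
  geometry: yes
- name: WID
  scale: continuous
  geometry: yes
- name: THI
  scale: continuous
  geometry: yes
- name: EPA
  scale: continuous
- name: SHA
  scale: nominal
  levels:
  - Convergent
  - Divergent
  - Round/oval
  - Parallel/sub-parallel
  - Rectangular
  codes:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
- name: BUL
  scale: ordinal
  levels:
  - Absent
  - Poor-developed
  - Developed
  - Shattered
  - Well-developed
  codes:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
- name: ESC
  scale: nominal
  levels:
  - Absent
  - Present
  codes:
  - '0'
  - '1'
- name: LIP
  scale: nominal
  levels:
  - Absent
  - Present
  codes:
  - '0'
  - '1'
- name: HCO
  scale: nominal
  levels:
  - Absent
  - Present
  codes:
  - '0'
  - '1'
- name: PTY
  scale: nominal
  levels:
  - Cortical
  - Plain
  - Facetted
  - Dihedral
  - Crushed/shattered
  - Linear/punctiform
  codes:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
  - '6'
- name: PWI
  scale: continuous
  geometry: yes
- name: PTH
  scale: continuous
  geometry: yes
- name: NNU
  scale: ordinal
  levels:
  - '0'
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
  - '6'
  - '7'
  - '8'
  - '9'
  codes:
  - '0'
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
  - '6'
  - '7'
  - '8'
  - '9'
- name: NOR
  scale: nominal
  levels:
  - Parallel
  - Opposed
  - Convergent
  - Orthogonal
  - Centripetal
  codes:
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
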