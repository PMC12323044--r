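genome: sacCer3.fa
layers:
- sir3_potential
- sir3_bound
factors:
- name: RAP1
  profile:
    kind: regex
    pattern: GGTGT.{0,3}GGTGT
    strand: forward
  predicate:
    present: []
    absent: []
    mode: any
  mods:
    sir3_potential: present
  statewidth: 10
  placement: statewidth
  cacheable: yes
- name: Sir3p
  profile:
    kind: none
  predicate:
    present:
    - sir3_potential
    absent:
    - sir3_bound
    mode: any
  mods:
    sir3_bound: present
  statewidth: 147
  placement: statewidth
  cacheable: no
- name: Sir3.spreader
  profile:
    kind: none
  predicate:
    present:
    - sir3_bound
    absent: []
    mode: any
  mods:
    sir3_bound: present
  statewidth: 147
  offset:
    dist: normal
    mean: 147.0
    sd: 30.0
  placement: statewidth
  cacheable: no
abundances:
  RAP1: 500.0
  Sir3p: 500.0
  Sir3.spreader: 500.0
n_cycles: 200
snapshot_every: 10
seed: 1
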