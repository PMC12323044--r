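genome: hg38.fa
layers:
- active
- repressed
factors:
- name: bf_OCT4
  profile:
    kind: consensus
    pattern: ATGCAAAT
    strand: both
  predicate:
    present: []
    absent: []
    mode: any
  mods:
    active: present
  statewidth: 10000
  placement: statewidth
  cacheable: yes
- name: bf_SOX2
  profile:
    kind: consensus
    pattern: WTTGT
    strand: both
  predicate:
    present: []
    absent: []
    mode: any
  mods:
    active: present
  statewidth: 10000
  placement: statewidth
  cacheable: yes
- name: bf_KLF4
  profile:
    kind: consensus
    pattern: GCCAMGCCTC
    strand: both
  predicate:
    present: []
    absent: []
    mode: any
  mods:
    active: present
  statewidth: 10000
  placement: statewidth
  cacheable: yes
- name: bf_MYC
  profile:
    kind: consensus
    pattern: CACGTG
    strand: both
  predicate:
    present: []
    absent: []
    mode: any
  mods:
    active: present
  statewidth: 10000
  placement: statewidth
  cacheable: yes
- name: bf_repressor
  profile:
    kind: regex
    pattern: (CG.{0,20}){4}CG
    strand: forward
  predicate:
    present: []
    absent:
    - active
    mode: any
  mods:
    repressed: present
  statewidth: 500
  placement: statewidth
  cacheable: yes
- name: bf.RepSpread
  profile:
    kind: none
  predicate:
    present:
    - repressed
    absent:
    - active
    mode: any
  mods:
    repressed: present
  statewidth: 1000
  offset:
    dist: uniform
    min: 1
    max: 1000
  placement: statewidth
  cacheable: no
- name: bf.cleaner
  profile:
    kind: none
  predicate:
    present:
    - active
    - repressed
    absent: []
    mode: any
  mods:
    active: absent
    repressed: absent
  placement: intersection
  cacheable: no
abundances:
  bf_OCT4: 5000.0
  bf_SOX2: 5000.0
  bf_KLF4: 5000.0
  bf_MYC: 5000.0
  bf_repressor: 20000.0
  bf.RepSpread: 20000.0
  bf.cleaner: 1.0e+10
n_cycles: 100
snapshot_every: 10
seed: 1
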