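# Tunable parameter space for StringTie (transcribed from the StringTie
# command-line documentation, release 2.x). Boolean parameters use
# presence-style flags. Re-check against `stringtie --help` when
# targeting a different release.
parameters:
- name: min_isoform_fraction
  kind: real
  default: 0.01
  lower: 0.0
  upper: 0.5
  step: 0.01
  flag: -f
- name: min_transcript_length
  kind: integer
  default: 200
  lower: 50
  upper: 1000
  step: 50
  flag: -m
- name: min_anchor_length
  kind: integer
  default: 10
  lower: 1
  upper: 50
  step: 2
  flag: -a
- name: min_junction_coverage
  kind: real
  default: 1.0
  lower: 0.0
  upper: 20.0
  step: 0.5
  flag: -j
- name: min_read_coverage
  kind: real
  default: 1.0
  lower: 0.1
  upper: 20.0
  step: 0.5
  flag: -c
- name: min_single_exon_coverage
  kind: real
  default: 4.75
  lower: 0.25
  upper: 20.0
  step: 0.25
  flag: -s
- name: gap_between_read_mappings
  kind: integer
  default: 50
  lower: 10
  upper: 500
  step: 10
  flag: -g
- name: max_multimap_fraction
  kind: real
  default: 0.95
  lower: 0.05
  upper: 1.0
  step: 0.05
  flag: -M
- name: disable_trimming
  kind: boolean
  default: false
  flag: -t
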