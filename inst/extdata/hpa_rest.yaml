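nodes:
- name: CRH
  max_level: 1
  input: no
- name: ACTH
  max_level: 1
  input: no
- name: CORT
  max_level: 2
  input: no
- name: R
  max_level: 2
  input: no
interactions:
- source: CORT
  target: CRH
  sign: '-'
  threshold: 1
- source: CRH
  target: ACTH
  sign: +
  threshold: 1
- source: R
  target: ACTH
  sign: '-'
  threshold: 1
- source: ACTH
  target: CORT
  sign: +
  threshold: 1
- source: CORT
  target: R
  sign: +
  threshold: 2
- source: R
  target: R
  sign: +
  threshold: 2
parameters:
  CRH:
  - context: []
    K: 0
  - context:
    - CORT
    K: 1
  ACTH:
  - context: []
    K: 0
  - context:
    - CRH
    K: 1
  - context:
    - CRH
    - R
    K: 1
  - context:
    - R
    K: 1
  CORT:
  - context: []
    K: 0
  - context:
    - ACTH
    K: 2
  R:
  - context: []
    K: 0
  - context:
    - CORT
    K: 1
  - context:
    - CORT
    - R
    K: 2
  - context:
    - R
    K: 2
update:
  scheme: priority
  delays:
    CRH: 1
    ACTH: 1
    CORT: 4
    R: 1
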