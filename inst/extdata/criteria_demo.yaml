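# A compact criteria registry: signed fraud points per criterion, negative
# for protective evidence, positive for suspicious evidence.
criteria:
  - name: freetext_sensical
    direction: protective
    points: -3
    evaluator: freetext
  - name: no_remuneration
    direction: protective
    points: -1
    evaluator: no_remuneration
  - name: nonsense_combo
    direction: suspicious
    points: 3
    evaluator: consistency
  - name: honeypot
    direction: suspicious
    points: 4
    evaluator: honeypot
  - name: fast_completion
    direction: suspicious
    points: 2
    evaluator: completion_time
    params: {threshold_s: 800}
  - name: email_pattern
    direction: suspicious
    points: 3
    evaluator: email_pattern
rules:
  - name: mfm_cfpc
    clauses:
      - {field: specialty, op: eq, value: mfm_subspecialist}
      - {field: college, op: eq, value: CFPC}
  - name: np_rcpsc
    clauses:
      - {field: specialty, op: eq, value: nurse_practitioner}
      - {field: college, op: eq, value: RCPSC}
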