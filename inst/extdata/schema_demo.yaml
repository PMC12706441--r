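# Declared question domains for the demonstration survey layout used by
# the synthetic cohort generator.
questions:
  specialty: [family_medicine, obgyn, mfm_subspecialist, nurse_practitioner]
  college: [CFPC, RCPSC, CNA, none]
  years_practice: numeric
  q_likert1: numeric
  q_likert2: numeric
  q_likert3: numeric
free_text: [ft_other_services]
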