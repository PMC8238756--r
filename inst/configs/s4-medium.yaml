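# Scenario S4 (a = 0.021, b = 0.082, sigma2 = 0.043), medium cohort.
scenario: S4
n_ref: 20000
ref_age: 90
truncation_ages: [60, 80, 85, 90]
alpha: 0.05
measures: [D, A, E, DA, I33]
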