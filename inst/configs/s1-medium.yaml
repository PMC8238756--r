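# Scenario S1 (a = 0.015, b = 0.085, sigma2 = 0.043), medium cohort:
# 20,000 survivors to ages 90+, sizes at other ages translated by survival.
scenario: S1
n_ref: 20000
ref_age: 90
truncation_ages: [60, 80, 85, 90]
alpha: 0.05
measures: [D, A, E, DA, I33]
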