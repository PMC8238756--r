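# Female parameter setting (point estimates a = 0.015, b = 0.085,
# sigma2 = 0.043) anchored at an observed cohort of 20,917 survivors to 90+.
name: female
a: 0.015
b: 0.085
sigma2: 0.043
n_ref: 20917
ref_age: 90
truncation_ages: [80, 82, 85, 90]
alpha: 0.05
measures: [DA]
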