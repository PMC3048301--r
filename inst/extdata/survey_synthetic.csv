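sex,age_class,prevalence,pct_treated,pct_known_untreated,pct_unknown
M,35-44,0.24,0.03,0.05,0.16
M,45-54,0.36,0.08,0.08,0.20
M,55-64,0.50,0.17,0.10,0.23
F,35-44,0.12,0.04,0.03,0.05
F,45-54,0.25,0.09,0.05,0.11
F,55-64,0.45,0.18,0.09,0.18
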