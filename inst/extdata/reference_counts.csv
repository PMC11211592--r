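label,type,x1,x2,x3,x4,published_estimate,published_lower,published_upper
autoimmune_hepatitis_vs_database,ror_external,634,353949,4566,49568379,19.34,17.80,21.02
immune_mediated_hepatitis_vs_database,ror_external,546,353949,350,49568379,217.24,189.95,248.45
hepatitis_fulminant_vs_database,ror_external,80,353949,2439,49568379,4.56,3.65,5.70
immune_mediated_pd1_pdl1_vs_ctla4,ror_head_to_head,336,268517,8,22903,3.59,1.78,6.18
immune_mediated_dual_vs_mono,ror_head_to_head,202,62530,344,291420,2.74,2.30,7.56
autoimmune_dual_vs_mono,ror_head_to_head,219,62530,415,291420,2.46,2.09,7.31
hepatitis_fulminant_dual_vs_mono,ror_head_to_head,22,62530,58,291420,1.74,1.06,4.81
hrae_nivolumab_vs_ipilimumab,ror_head_to_head,576,471495,179,123792,0.84,0.71,1.00
hrae_pembrolizumab_vs_ipilimumab,ror_head_to_head,320,298395,179,123792,0.74,0.62,0.89
hrae_atezolizumab_vs_ipilimumab,ror_head_to_head,111,104568,179,123792,0.73,0.58,0.93
hrae_durvalumab_vs_ipilimumab,ror_head_to_head,38,43278,179,123792,0.61,0.43,0.86
hrae_cemiplimab_vs_ipilimumab,ror_head_to_head,22,9906,179,123792,1.54,0.99,2.39
hrae_avelumab_vs_ipilimumab,ror_head_to_head,13,6798,179,123792,1.32,0.75,2.32
dual_vs_mono_trial_incidence,relative_risk,6.5,3.8,,,1.71,,
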