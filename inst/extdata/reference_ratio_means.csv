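measure,sex,n,mean,sd,z,p
rostrum,male,61,0.013,0.007,0.65,0.511
rostrum,female,53,0.013,0.005,0.65,0.511
genu,male,61,0.093,0.026,2.24,0.025
genu,female,53,0.103,0.022,2.24,0.025
rostral_body,male,61,0.067,0.012,0.54,0.587
rostral_body,female,53,0.068,0.012,0.54,0.587
anterior_midbody,male,61,0.048,0.010,0.85,0.396
anterior_midbody,female,53,0.050,0.009,0.85,0.396
posterior_midbody,male,61,0.043,0.009,2.19,0.028
posterior_midbody,female,53,0.047,0.012,2.19,0.028
isthmus,male,61,0.032,0.009,1.6,0.11
isthmus,female,53,0.035,0.009,1.6,0.11
splenium,male,61,0.124,0.025,1.96,0.05
splenium,female,53,0.135,0.026,1.96,0.05
total_cc,male,61,0.420,0.076,2.08,0.037
total_cc,female,53,0.451,0.073,2.08,0.037
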