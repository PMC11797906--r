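sex,n_patients,mean_age_years
male,823,47.04
female,1177,45.27
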