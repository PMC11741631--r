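stratum,covered_patient_days,total_patient_days
critical,112000,112000
non_critical,249895.80000000002,378000
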