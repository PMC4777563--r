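service,allocated_millions,remaining_millions,pct_allocated
all_services,11815.3,5387.7,68.7
emergency,251.8,192.3,56.7
inpatient_acute_combined,8194.5,0,100.0
inpatient_nonacute,0.0,5.3,0.0
inpatient_rehab,434.6,23.1,94.9
complex_continuing_care,358.3,139.5,72.0
long_term_care,187.9,254.9,42.4
home_care,406.0,1031.8,28.2
dialysis_outpatient,124.3,638.9,16.3
oncology_outpatient,86.5,517.7,14.3
physician_laboratory,1530.2,989.2,60.4
drug,241.2,1503.2,13.8
assistive_device,0.3,2.8,9.0
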