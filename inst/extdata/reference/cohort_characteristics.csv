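characteristic,category,n,percent,denominator
age_group,0-17,28070,4.8,587982
age_group,18-44,89232,15.2,587982
age_group,45-64,164182,27.9,587982
age_group,65-84,239453,40.7,587982
age_group,85+,67045,11.4,587982
sex,female,314550,53.5,587982
sex,male,273432,46.5,587982
rurality,urban,526441,89.5,587982
rurality,rural,55785,9.5,587982
rurality,missing,5756,1.0,587982
primary_care_model,family_health_team,111375,17.9,587982
primary_care_model,fee_for_service,346908,59.0,587982
primary_care_model,capitation,125935,21.4,587982
primary_care_model,other,9754,1.6,587982
upc,no_contact,33640,5.7,587982
upc,low,456845,77.7,587982
upc,high,97497,16.6,587982
morbidity,no_contact,14197,2.4,587982
morbidity,0_adgs,2815,0.5,587982
morbidity,1-7_adgs,227298,38.7,587982
morbidity,8plus_adgs,343672,58.5,587982
drug_benefit,not_eligible,281484,47.9,587982
drug_benefit,eligible,306498,52.1,587982
drug_count_eligible,0,8239,2.7,306498
drug_count_eligible,1-5,54573,17.8,306498
drug_count_eligible,6-9,76085,24.8,306498
drug_count_eligible,10-19,135226,44.1,306498
drug_count_eligible,20+,32375,10.6,306498
palliative,yes,68996,11.7,587982
died,yes,52999,9.0,587982
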