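grouping,n,percent,mean_cost,sd_cost,median_cost,q1_cost,q3_cost,total_millions,pct_total
all_pce,697059,100,30961,38069,18251,12160,33978,11815.3,100
post_admission_events,75126,10.8,36303,52279,20687,12207,39579,2727.3,23.1
acute_unplanned_medical,146079,21.0,17057,23515,9505,6373,17981,2491.6,21.1
acute_planned_surgical,245329,35.2,7717,12291,3865,1712,10919,1893.3,16.0
mental_illness_addictions,41327,5.9,30948,44262,17224,10325,32126,1279.0,10.8
trauma_injury_poisoning,44326,6.4,26971,34807,15753,8947,31731,1195.5,10.1
cancer,51825,7.4,13521,18500,9073,4113,15298,700.7,5.9
acute_unplanned_surgical,28574,4.1,18676,22155,13647,8900,19356,533.6,4.5
acsc,26911,3.9,14719,20987,8416,6022,14750,396.1,3.4
perinatal_congenital_lbw,10714,1.5,27491,42026,15492,9863,29135,294.5,2.5
pregnancy,18095,2.6,8095,6552,7255,5243,8974,146.5,1.2
acute_planned_medical,7783,1.1,17281,25539,9679,5759,18839,134.5,1.1
other_causes,970,0.1,23283,33368,11965,4912,26509,22.6,0.2
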