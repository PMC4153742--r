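term,estimate,se
const,39.530,1.577
temp_low,0.218,0.021
temp_high,2.139,0.019
precipitation,-0.010,0.001
doy,-0.107,0.001
year,-0.165,0.018
road_low,-0.255,0.098
road_high,-1.074,0.219
lat_low,-0.123,0.038
lat_high,0.003,0.003
sigma_u,2.464,NA
sigma_e,8.904,NA
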