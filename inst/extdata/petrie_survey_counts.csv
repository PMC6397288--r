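survey_id,role,k_obs,k_auto,k_manual
North 1,training,19,13,9
North 2,training,20,15,11
North 3,training,20,20,11
North 4,testing,15,14,10
North 5,testing,18,17,13
North 6,testing,19,15,12
South 1,training,5,5,2
South 2,training,11,11,6
South 3,testing,9,7,5
South 4,testing,11,9,6
South 5,testing,6,6,3
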