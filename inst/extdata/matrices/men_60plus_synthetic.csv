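starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,58,8,10,6,4,11,3
iso_overweight,16,44,4,4,1,23,8
iso_hypertension,0,0,64,0,0,30,6
iso_dyslipidemia,20,2,4,34,3,30,7
iso_hyperglycemia,0,0,0,0,50,32,18
two_component,0.5,2,9,1.5,1.5,59,26.5
ms,0,0,2.5,0,0.5,20,77
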