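starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,82.05,5.45,3.7,4.61,0.84,2.65,0.7
iso_overweight,27.5,54.16,1.25,4.17,0.42,11.25,1.25
iso_hypertension,0,0,86.8,0,0,11.46,1.74
iso_dyslipidemia,38.25,3.48,3.48,42.61,0,9.57,2.61
iso_hyperglycemia,0,0,0,0,73.81,19.05,7.14
two_component,3.16,3.95,21.34,3.16,3.95,49.02,15.42
ms,0,0,4.88,0,2.44,36.59,56.09
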