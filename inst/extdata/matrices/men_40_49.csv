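starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,68.15,8.3,4.26,10.54,1.57,5.72,1.46
iso_overweight,13.17,52.23,0,3.13,0.22,25.45,5.8
iso_hypertension,0,0,64.71,0,0,27.01,8.29
iso_dyslipidemia,24.82,4.61,3.19,37.59,1.06,23.05,5.67
iso_hyperglycemia,0,0,0,0,56.9,31.03,12.07
two_component,1.28,4.81,8.49,3.13,1.44,57.69,23.16
ms,0,0,2.6,0,0.21,22.56,74.64
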