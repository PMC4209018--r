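starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,62.71,9.9,5.94,7.92,3.96,7.59,1.98
iso_overweight,18.62,46.28,2.66,4.79,0.53,20.21,6.91
iso_hypertension,0,0,66.4,0,0,29.25,4.35
iso_dyslipidemia,22.97,1.35,1.35,36.49,2.7,29.73,5.41
iso_hyperglycemia,0,0,0,0,53.57,30.36,16.07
two_component,0.53,2.79,7.85,1.6,1.33,60.24,25.66
ms,0,0,2.13,0,0.15,21.46,76.26
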