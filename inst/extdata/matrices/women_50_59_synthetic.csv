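starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,70,5.5,8.5,5,1.5,8,1.5
iso_overweight,22,46,3,4,0.5,18,6.5
iso_hypertension,0,0,74,0,0,21.5,4.5
iso_dyslipidemia,28,3,4,38,1,22,4
iso_hyperglycemia,0,0,0,0,62,24,14
two_component,1.5,3,14,2.5,2.5,55,21.5
ms,0,0,4,0,1,28,67
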