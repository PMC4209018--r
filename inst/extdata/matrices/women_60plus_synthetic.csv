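starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,62,5,12,5,2,12,2
iso_overweight,18,45,5,3.5,1,20,7.5
iso_hypertension,0,0,70,0,0,24.5,5.5
iso_dyslipidemia,24,2.5,6,35,1.5,26,5
iso_hyperglycemia,0,0,0,0,56,27,17
two_component,1,2.5,13.5,2,2,56,23
ms,0,0,3.5,0,1,25.5,70
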