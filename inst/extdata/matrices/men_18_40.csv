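starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,72.07,9.48,4.55,7.68,0.58,4.55,1.09
iso_overweight,13.51,52.25,1.03,3.35,0.51,24.07,5.28
iso_hypertension,0,0,61.21,0,0,26.67,12.12
iso_dyslipidemia,23.21,3.27,1.79,42.86,0.3,22.32,6.25
iso_hyperglycemia,0,0,0,0,48.57,31.43,20
two_component,3.33,9.07,9.44,2.5,0.83,54.17,20.65
ms,0,0,3.78,0,0,23.92,72.3
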