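starting_state,no_component,iso_overweight,iso_hypertension,iso_dyslipidemia,iso_hyperglycemia,two_component,ms
no_component,86.38,3.71,2.15,3.76,0.8,2.3,0.9
iso_overweight,37.81,44.27,0.5,4.98,0.5,9.45,2.49
iso_hypertension,0,0,83.82,0,0,13.24,2.94
iso_dyslipidemia,47.57,5.83,2.91,25.24,0.97,10.68,6.8
iso_hyperglycemia,0,0,0,0,88.64,9.09,2.27
two_component,7.69,6.51,20.71,2.37,3.55,46.74,12.43
ms,0,0,25,0,0,42.31,32.69
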