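patient_id,group,minutes
P01,manual,62.5
P01,adjusted,18
P01,processing,9.5
P02,manual,48
P02,adjusted,15.5
P02,processing,11
P03,manual,71.5
P03,adjusted,21
P03,processing,10
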