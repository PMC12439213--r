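Structure: Brainstem
Min Dose [Gy]: 2.1
Max Dose [Gy]: 48.7
Mean Dose [Gy]: 21.4
Median Dose [Gy]: 19.8

Structure: Parotid_L
Min Dose [Gy]: 4.3
Max Dose [Gy]: 61.2
Mean Dose [Gy]: 25.6
Median Dose [Gy]: 23.0
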