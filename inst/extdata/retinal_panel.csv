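approach,accuracy,sensitivity,sensitivity_medium_plus,sensitivity_high,specificity,ppv,f1
resident,75.2,51.9,63.0,80.5,90.4,77.9,62.3
ai,88.1,76.3,90.1,100.0,95.8,92.2,83.5
synergy,86.1,84.0,92.6,100.0,87.4,81.4,82.6
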