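approach,accuracy,sensitivity,specificity,ppv,f1
resident,82.9,50.0,90.5,54.8,52.3
ai,88.6,63.0,94.5,72.5,67.4
synergy,85.3,80.4,86.4,57.8,67.3
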