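resident_cataract,ai_opacity,count
FALSE,FALSE,360
FALSE,TRUE,35
TRUE,FALSE,26
TRUE,TRUE,14
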