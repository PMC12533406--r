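source	heterotrimer	specificity
predicted	ABC-1	16.0
predicted	ABC-2	26.3
predicted	AAB-FOGER	17.4
predicted	ABC-FOGER	22.6
experimental	ABC-1	13.5
experimental	ABC-2	16.0
experimental	AAB-FOGER	16.0
experimental	ABC-FOGER	14.5
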