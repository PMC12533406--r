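heterotrimer	predicted	experimental	deviation
ABC-1	39.7	33.5	6.2
ABC-2	63.9	38.5	25.4
AAB-FOGER	45.8	34.5	11.3
ABC-FOGER	47.5	40.7	6.8
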