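heterotrimer	species	tm	floored	register
ABC-1	A	11.0	FALSE	NA
ABC-1	B	10.0	TRUE	NA
ABC-1	C	10.0	TRUE	NA
ABC-1	AB	19.5	FALSE	NA
ABC-1	AC	17.5	FALSE	NA
ABC-1	BC	20.0	FALSE	NA
ABC-1	ABC	33.5	FALSE	NA
ABC-2	A	10.0	TRUE	NA
ABC-2	B	17.0	FALSE	NA
ABC-2	C	10.0	TRUE	NA
ABC-2	AB	22.5	FALSE	NA
ABC-2	AC	15.5	FALSE	NA
ABC-2	BC	21.0	FALSE	NA
ABC-2	ABC	38.5	FALSE	NA
AAB-FOGER	A	18.5	FALSE	NA
AAB-FOGER	B	14.5	FALSE	NA
AAB-FOGER	AB	34.5	FALSE	NA
ABC-FOGER	A	10.0	TRUE	NA
ABC-FOGER	B	10.0	TRUE	NA
ABC-FOGER	C	13.0	FALSE	NA
ABC-FOGER	AB	20.0	FALSE	NA
ABC-FOGER	AC	26.0	FALSE	NA
ABC-FOGER	BC	21.5	FALSE	NA
ABC-FOGER	ABC	40.5	FALSE	NA
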