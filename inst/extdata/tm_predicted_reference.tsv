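heterotrimer	species	tm	floored	register
ABC-1	A	10.0	TRUE	NA
ABC-1	B	10.0	TRUE	NA
ABC-1	C	10.0	TRUE	NA
ABC-1	AB	23.6	FALSE	{ABB}
ABC-1	AC	14.0	FALSE	{AAC}
ABC-1	BC	23.7	FALSE	{BCC}
ABC-1	ABC	39.7	FALSE	{ABC}
ABC-2	A	14.3	FALSE	NA
ABC-2	B	15.1	FALSE	NA
ABC-2	C	17.7	FALSE	NA
ABC-2	AB	33.7	FALSE	{AAB}
ABC-2	AC	28.3	FALSE	{ACC}
ABC-2	BC	37.6	FALSE	{CBC}
ABC-2	ABC	63.9	FALSE	{ABC}
AAB-FOGER	A	28.4	FALSE	NA
AAB-FOGER	B	10.0	TRUE	NA
AAB-FOGER	AB	45.8	FALSE	{AAB}
ABC-FOGER	A	10.0	TRUE	NA
ABC-FOGER	B	10.0	TRUE	NA
ABC-FOGER	C	14.0	FALSE	NA
ABC-FOGER	AB	22.8	FALSE	{ABB}
ABC-FOGER	AC	22.9	FALSE	{ACC}
ABC-FOGER	BC	24.9	FALSE	{CBC}
ABC-FOGER	ABC	47.5	FALSE	{ABC}
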