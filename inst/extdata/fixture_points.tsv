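Start (f)	End (f)	Duration (f)	Duration (s)	Winner	Points A	Points B	Top Left	Top Right	Bottom Left	Bottom Right
13,606	13,820	214	7.1	B	0	15	L Sainz	G Triay	A Sánchez	A Salazar
14,093	14,785	692	23.1	T	15	15	L Sainz	G Triay	A Sánchez	A Salazar
15,332	16,204	872	29.1	T	30	15	L Sainz	G Triay	A Sánchez	A Salazar
16,932	17,004	72	2.4	B	30	30	L Sainz	G Triay	A Sánchez	A Salazar
17,378	17,661	283	9.4	B	30	40	L Sainz	G Triay	A Sánchez	A Salazar
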