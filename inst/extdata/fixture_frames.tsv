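Frame	TL i	TL j	TR i	TR j	BL i	BL j	BR i	BR j	TL x	TL y	TR x	TR y	BL x	BL y	BR x	BR y
13,614	478	202	785	266	401	554	911	553	1.89	18.53	7.49	13.60	2.50	1.60	7.87	1.66
13,615	477	202	785	266	401	555	912	554	1.87	18.52	7.49	13.60	2.50	1.59	7.88	1.62
13,616	477	203	785	266	400	553	914	555	1.89	18.43	7.49	13.60	2.49	1.63	7.89	1.60
13,617	479	204	785	266	399	550	915	556	1.94	18.35	7.49	13.59	2.47	1.70	7.90	1.57
13,618	480	206	785	266	398	549	918	556	1.96	18.21	7.49	13.59	2.46	1.74	7.93	1.58
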