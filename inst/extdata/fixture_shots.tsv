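Frame	Player	Shot Type	Lob
13,604	TL	Serve	F
13,633	BR	D	T
13,656	TL	B	F
13,676	BR	D	F
13,696	TL	VD	F
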