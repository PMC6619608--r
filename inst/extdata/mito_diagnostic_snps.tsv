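site_id	EH77	EH78	EH79	EH80	EH83	EH105	EH84	EH85	EH86	EH90	EH91	EH103	EH92	EH93	EH94	EH96	EH97	EH98	EH104	Picea_glauca
sc01_1023485	A	A	A	A	A	-	A	A	A	A	A	A	C	C	C	C	C	C	C	G
sc04_65316	G	G	-	G	G	G	-	G	-	-	G	-	T	T	T	T	T	-	T	G
sc06_194010	-	A	A	A	A	A	-	A	-	A	A	A	C	C	C	C	C	C	-	C
sc06_325675	C	C	C	C	-	-	-	-	C	C	C	C	A	-	A	A	A	A	A	C
sc11_95116	A	A	-	A	A	A	A	A	A	-	A	-	G	G	G	G	G	G	G	A
sc15_5654	A	A	A	A	A	A	-	A	A	A	A	A	-	-	C	C	C	C	C	A
sc17_36760	-	C	-	-	C	-	C	-	C	C	-	-	T	-	T	-	T	T	T	C
sc20_27703	A	A	-	A	-	-	-	-	-	A	A	A	C	-	C	-	C	C	C	A
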