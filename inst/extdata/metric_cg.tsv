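	C	G	-
C	0	2	1
G	2	0	1
-	1	1	0
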