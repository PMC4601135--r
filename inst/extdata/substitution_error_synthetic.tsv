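from	to	count
A	C	520
A	G	1630
A	T	410
C	A	640
C	G	380
C	T	1980
G	A	2010
G	C	360
G	T	620
T	A	430
T	C	1570
T	G	540
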