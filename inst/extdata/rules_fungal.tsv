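subfamily	tm2	tm5	le1	le2	require_r_le2	max_mw	npa_pct
Fps1-like	W	L,I,M,N	T,C,A,S	R	TRUE	NA	61.7
Yfl054-like	W	A,S,T,G,D	G,A	R	TRUE	NA	66.7
Yfl054-like	W	V,I	G	R	TRUE	NA	NA
Yfl054-like	W	M	L	R	TRUE	NA	NA
Yfl054-like	W	G	F,Y	R	TRUE	NA	NA
alpha	W	G	Y,W,F	R	TRUE	NA	95.8
beta	W	G	Y	R	TRUE	NA	12.5
gamma1	T,N,S	C,T	F	R	TRUE	NA	20
gamma2	W,M,I	G	Y	R	TRUE	NA	0
delta	F,Y,M	V,I,A	I,L,V	R	TRUE	NA	100
AQP	F,M,A	H	T,A,C,S	R	TRUE	NA	28.8
AQP	F,I,A	E	G	R	TRUE	NA	NA
AQP	Y,F	M,L,V,A	A,G	R	TRUE	NA	NA
AQP	F,M	Q	C,G	R	TRUE	NA	NA
XIP	N,S,A	S,A,G	A,F	R,K	FALSE	NA	82.4
SIP-like	V,I,L,M	A,S,G	G	L,I	FALSE	28800	81.2
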