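subfamily	tm2	tm5	le1	le2	require_r_le2	max_mw	npa_pct
TIP	H	I,V,M	A,G,S	R	TRUE	NA	1.1
TIP	H	I,V	A	V,L,I	FALSE	NA	NA
TIP	H,Q,N	T,S,A	A	R	TRUE	NA	NA
TIP	Q	V	A	R	TRUE	NA	NA
TIP	H	V	G	C	FALSE	NA	NA
SIP	V,F,I,L	V,I	P	N	FALSE	NA	84.0
SIP	S,T,Y	H	G	S,A	FALSE	NA	NA
SIP	I,V	V,F	P	I,F	FALSE	NA	NA
SIP	A,S	V	P	N	FALSE	NA	NA
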