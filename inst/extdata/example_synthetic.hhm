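HHsearch 1.5
NAME  example profile (synthetic)
SEQ
HMM    A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
       M->M	M->I	M->D	I->M	I->I	D->M	D->D	Neff	Neff_I	Neff_D
G 1	10038	7306	5159	9045	4711	1270	7762	7966	3773	3292	7550	2678	9149	14305	5504	8929	4778	4774	7491	4056	1
       0	*	*	*	*	*	*	1000	0	0
A 2	2285	13694	6627	7192	6902	3283	5478	5785	6120	11148	4390	3553	5429	3008	5246	5820	9401	3071	4052	3238	2
       0	*	*	*	*	*	*	1000	0	0
T 3	7435	5008	3485	4284	5068	5094	4807	5656	7643	3452	5393	3319	2950	5789	6164	3351	2487	5844	7556	5211	3
       0	*	*	*	*	*	*	1000	0	0
//
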