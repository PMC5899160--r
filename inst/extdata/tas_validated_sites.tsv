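chrom	pos	ref	alt	gene	carrier	effect	wes_aaf_carrier	tas_aaf_carrier	tas_aaf_cotwin	pyro_aaf_carrier	pyro_aaf_cotwin
chr7	105641974	G	T	CDHR3	TT11	synonymous_variant	4.30	2.417	0.012	0	0
chr11	72947061	C	T	P2RY2	TT11	3_prime_UTR_variant	9.20	5.770	0.010	11	0
chr12	22040794	A	C	ABCC9	TT11	missense_variant	8.10	7.320	0.007	11	0
chr1	21605869	G	A	ECE1	TT12	missense_variant	6.3	3.830	0.014	5	0
chr1	39991592	C	T	BMP8A	TT12	3_prime_UTR_variant	11.3	6.588	0.006	8	0
chr1	245849059	C	T	KIF26B	TT12	missense_variant	5.5	1.120	0.012	0	0
chr12	78571018	C	T	NAV3	TT12	missense_variant	5.8	3.092	0.016	3	0
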