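bloc_id	snp_id	allele	chrom	pos
thop1	rs10409851	A	19	2101000
thop1	kgp1758027	C	19	2104000
thop1	rs4806874	A	19	2107000
thop1	rs10415622	A	19	2110000
thop1	kgp553088	C	19	2113000
thop1	rs12608998	G	19	2116000
thop1	rs8105402	C	19	2119000
thop1	kgp4303224	G	19	2122000
thop1	kgp5034493	C	19	2125000
thop1	rs7008	A	19	2128000
thop1	rs2238614	G	19	2131000
thop1	rs1860938	A	19	2134000
thop1	kgp8397108	A	19	2137000
thop1	rs2110118	T	19	2140000
thop1	rs4807330	G	19	2143000
thop1	rs1640262	T	19	2146000
thop1	kgp5523730	A	19	2149000
thop1	rs1736192	G	19	2152000
thop1	kgp7878898	G	19	2155000
thop1	kgp726867	T	19	2158000
thop1	rs2260416	G	19	2161000
thop1	rs1736181	C	19	2164000
thop1	rs1640271	C	19	2167000
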