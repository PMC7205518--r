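system	subtype	marker_name	accessions	canonical
RM	RM type I	hsdM	MRK0101,MRK0102	1
RM	RM type I	hsdR	MRK0103	1
RM	RM type I	hsdS	MRK0104	1
RM	RM type II	mtaseII	MRK0105,MRK0999	1
RM	RM type II	reaseII	MRK0106	1
RM	RM type III	modIII	MRK0107	1
RM	RM type III	resIII	MRK0108	1
RM	RM type IV	mcrB	MRK0109	1
BREX	BREX type 1	brxA	MRK0201	0
BREX	BREX type 1	brxB	MRK0202	0
BREX	BREX type 1	brxC	MRK0203	0
BREX	BREX type 1	pglX	MRK0204	0
BREX	BREX type 1	pglZ	MRK0205	0
BREX	BREX type 2	pglW	MRK0206	0
BREX	BREX type 2	pglY	MRK0207	0
BREX	BREX type 3	brxHI	MRK0208	0
DISARM	DISARM class 1	drmD	MRK0301	0
DISARM	DISARM class 1	drmMI	MRK0302	0
DISARM	DISARM class 2	drmA	MRK0303	0
DISARM	DISARM class 2	drmB	MRK0304	0
DISARM	DISARM class 2	drmC	MRK0305	0
DISARM	DISARM class 2	drmE	MRK0306	0
DISARM	DISARM class 2	drmMII	MRK0307,MRK0999	0
Abi	AbiE	abiEii	MRK0401	1
Abi	AbiQ	abiQ	MRK0402	1
Zorya	Zorya type I	zorA	MRK0501	0
Zorya	Zorya type I	zorB	MRK0502	0
Zorya	Zorya type I	zorC	MRK0503	0
Zorya	Zorya type II	zorD	MRK0504	0
Thoeris		thsA	MRK0601	0
Thoeris		thsB	MRK0602	0
Shedu		sduA	MRK0701	0
Gabija		gajA	MRK0801	0
Gabija		gajB	MRK0802	0
Hachiman		hamA	MRK0901	0
Hachiman		hamB	MRK0902	0
CRISPR		cas1	CAS0001	1
CRISPR		cas2	CAS0002	1
CRISPR		cas3	CAS0003	1
CRISPR		cas4	CAS0004	1
CRISPR		cas5	CAS0005	1
CRISPR		cas6	CAS0006	1
CRISPR		cas7	CAS0007	1
CRISPR		cas8a	CAS0081	1
CRISPR		cas8b	CAS0082	1
CRISPR		cas8c	CAS0083	1
CRISPR		cse1	CAS0084	1
CRISPR		csy1	CAS0085	1
CRISPR		cas9	CAS0009	1
CRISPR		cas10	CAS0010	1
CRISPR		csm2	CAS0011	1
CRISPR		cmr5	CAS0012	1
CRISPR		csn2	CAS0013	1
CRISPR		GSU0054	CAS0054	1
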