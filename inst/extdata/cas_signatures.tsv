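accession	type	subtype	priority
CAS0003	I		100
CAS0009	II		101
CAS0010	III		102
CAS0081	I	I-A	10
CAS0082	I	I-B	11
CAS0083	I	I-C	12
CAS0084	I	I-E	13
CAS0085	I	I-F	14
CAS0054	I	I-U	15
CAS0013	II	II-A	20
CAS0011	III	III-A	30
CAS0012	III	III-B	31
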