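ethnicity	race	AFR	EUR	ASN	AMR	SAN
Hispanic	African American	5	0	0	1	0
Non-Hispanic	African American	29	0	0	0	1
Hispanic	American Indian or Alaska Native	0	0	0	2	0
Non-Hispanic	American Indian or Alaska Native	0	0	0	2	1
Non-Hispanic	Asian	0	0	12	0	9
Non-Hispanic	Native Hawaiian or Other Pacific Islander	0	0	4	0	0
Hispanic	White	0	8	0	42	0
Non-Hispanic	White	0	427	0	3	0
Hispanic	Other	1	1	0	60	0
Non-Hispanic	Other	1	1	0	1	1
Hispanic	Multiracial	1	1	0	2	0
Non-Hispanic	Multiracial	3	9	7	2	3
Unknown	Multiracial	0	0	0	1	0
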