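provirus	type	length_bp	accession	cytoband	ucsc_span
K101	I	9175	AF164609	22q11.21	18,926,187–18,935,361
K102	I	9180	AF164610	1q22	155,596,457–155,605,636
K103	I	968	AF164611	10p12.1	27,182,399–27,183,366
K104	II	9446	AF164612	5p13.3	30,486,760–30,496,205
K106	I	9159	AF165240	3q13.2	112,743,124–112,752,282
K107	I	9180	AF164613	5q33.3	156,084,717–156,093,896
K108	II	17975	AF164614	7p22.1	4,622,057–4,640,031
K109	II	9422	AF164615	6q14.1	78,426,662–78,436,083
K110	I	9232	AF165258	1q23.3	160,660,575–160,669,806
K111	I	9160	GU476554	11q23.3	118,591,724–118,600,883
K112	II	9463	DQ112100	10p14	6,866,141–6,875,603
K114	II	9466	DQ112101	11q22.1	101,565,794–101,575,259
K117	II	9457	DQ112140	12q14.1	58,721,242–58,730,698
K118	I	9123	AB047240.1	3q12.3	101,410,737–101,419,859
K(I)	II	9138	AB047209	3q21.2	125,609,302–125,618,439
K4	I	6373	DQ112097	1p31.1	75,842,771–75,849,143
K5	I	7229	DQ112093	4q32.3	165,916,840–165,924,068
K50F	II	9518	DQ112151	19q13.12	37,597,549–37,607,066
K51	I	6738	DQ112098	19p12	22,757,824–22,764,561
K60	I	9657	DQ112108	21q21.1	19,935,621–19,940,996
K17B	II	9584	DQ112124	4p16.1	9,123,515–9,133,075
K7	II	9554	DQ112131	11p15.4	3,468,656–3,478,209
K27	II	10117	DQ112118	8p23.1	8,054,700–8,064,221
KO1D130352	II	9516	DQ112134	8p23.1	12,316,492–12,326,007
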