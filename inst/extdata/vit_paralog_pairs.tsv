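species	gene_a	gene_b	ks	published_mya	published_type
Solanum_lycopersicum	Solyc01g104780.2	Solyc01g104830.2	0.78947	26.32	tandem
Solanum_lycopersicum	Solyc01g104830.2	Solyc01g104820.2	0.61314	20.44	tandem
Solanum_lycopersicum	Solyc01g104820.2	Solyc01g104810.2	0.52749	17.58	tandem
Solanum_lycopersicum	Solyc01g104810.2	Solyc01g104800.2	0.34785	11.59	tandem
Solanum_lycopersicum	Solyc01g091850.2	Solyc04g008060.2	0.87754	29.25	transposition
Glycine_max	Glyma.08G075900	Glyma.08G076300	1.25353	41.78	tandem
Glycine_max	Glyma.08G075900	Glyma.08G076100	0.65802	21.93	tandem
Glycine_max	Glyma.08G076300	Glyma.08G076200	0.16939	5.65	tandem
Glycine_max	Glyma.08G076100	Glyma.08G076000	0.18062	6.02	tandem
Glycine_max	Glyma.08G076300	Glyma.05G121600	0.14334	4.78	segmental
Glycine_max	Glyma.08G076200	Glyma.05G121500	0.08789	2.93	segmental
Glycine_max	Glyma.08G076100	Glyma.05G121400	0.16184	5.39	segmental
Glycine_max	Glyma.08G076000	Glyma.05G121300	0.1751	5.84	segmental
Glycine_max	Glyma.08G075900	Glyma.05G121200	0.19831	6.61	segmental
Glycine_max	Glyma.08G047500	Glyma.05G240600	0.10616	3.54	transposition
Glycine_max	Glyma.08G181900	Glyma.15G050400	0.34178	11.39	transposition
Glycine_max	Glyma.20G166100	Glyma.10G225900	0.12651	4.22	transposition
Glycine_max	Glyma.16G168200	Glyma.02G082500	0.09795	3.27	transposition
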