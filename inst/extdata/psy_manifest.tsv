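name	accession	species
AtPSY1	Q941C7	Arabidopsis thaliana
AtPSY2	Q8LE92	Arabidopsis thaliana
AtPSY3	Q8S8P7	Arabidopsis thaliana
AtPSY4	B3H674	Arabidopsis thaliana
AtPSY5	Q1G3G7	Arabidopsis thaliana
AtPSY6	A0MDK8	Arabidopsis thaliana
AtPSY7	Q3E7N2	Arabidopsis thaliana
AtPSY8	Q9SN87	Arabidopsis thaliana
AmtPSY	W1PCD7	Amborella trichopoda
OsPSY1	A2ZX08	Oryza sativa
OsPSY2	Q5TKN9	Oryza sativa
OsPSY3	Q5NBP8	Oryza sativa
OsPSY4	Q9LDG6	Oryza sativa
OsPSY5	Q5N756	Oryza sativa
OsPSY6	Q75KZ0	Oryza sativa
OsPSY7	B9FKV0	Oryza sativa
ZmPSY1	B6TP25	Zea mays
ZmPSY2	B6U638	Zea mays
ZmPSY3	B6SX29	Zea mays
ZmPSY4	B6UG95	Zea mays
ZmPSY5	B6TWC1	Zea mays
ZmPSY6	B6SJ20	Zea mays
ZmPSY7	B6SK20	Zea mays
ZmPSY8	B6T2H1	Zea mays
GmPSY1	C6T043	Glycine max
GmPSY2	C6SWX4	Glycine max
GmPSY3	C6T324	Glycine max
CaPSY1	Q8GTD8	Cicer arietinum
LjPSY1	I3SPZ1	Lotus japonicus
PtPSY1	A9P872	Populus trichocarpa
MtPSY1	A2Q4B1	Medicago truncatula
PpPSY	A0A2K1K614	Physcomitrella patens
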