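id	name	formula
CPD0001	Tris(heptafluorobutanoyloxymethyl)propyl heptafluorobutanoate (PFAS)	C21H8F28O8
CPD0002	Dammarenediol II	C30H52O2
CPD0003	1,2-Diacylglycerol (34:3)	C37H66O5
CPD0004	Ergocalciferol (vitamin D2)	C28H44O
CPD0005	Cholest-5-ene	C27H46
CPD0006	Cholesterol	C27H46O
CPD0007	D-Glucose	C6H12O6
CPD0008	Caffeine	C8H10N4O2
CPD0009	L-Tryptophan	C11H12N2O2
CPD0010	Palmitic acid	C16H32O2
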