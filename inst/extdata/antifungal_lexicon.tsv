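# Study-drug lexicon: canonical name <TAB> synonym (generic, brand or
# salt variant). Matching is token-level case-insensitive containment
# against free-text drug names. Lines starting with '#' are ignored.
ketoconazole	ketoconazole
ketoconazole	nizoral
ketoconazole	extina
ketoconazole	xolegel
miconazole	miconazole
miconazole	miconazole nitrate
miconazole	monistat
miconazole	daktarin
miconazole	oravig
miconazole	micatin
clotrimazole	clotrimazole
clotrimazole	canesten
clotrimazole	lotrimin
clotrimazole	mycelex
fluconazole	fluconazole
fluconazole	diflucan
voriconazole	voriconazole
voriconazole	vfend
itraconazole	itraconazole
itraconazole	sporanox
itraconazole	onmel
itraconazole	tolsura
isavuconazole	isavuconazole
isavuconazole	isavuconazonium
isavuconazole	isavuconazonium sulfate
isavuconazole	cresemba
posaconazole	posaconazole
posaconazole	noxafil
caspofungin	caspofungin
caspofungin	caspofungin acetate
caspofungin	cancidas
micafungin	micafungin
micafungin	micafungin sodium
micafungin	mycamine
anidulafungin	anidulafungin
anidulafungin	eraxis
anidulafungin	ecalta
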