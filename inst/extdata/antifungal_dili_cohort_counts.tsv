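# Marginal category counts of a published FAERS antifungal-associated
# DILI cohort (2943 deduplicated reports, 2004 Q1 - 2021 Q3), used to
# build a fixture cohort and to parameterise the cohort-like synthetic
# generator. dimension <TAB> category <TAB> count.
dimension	category	count
age_band	<18	218
age_band	18-44	511
age_band	45-64	755
age_band	65-74	432
age_band	75-84	264
age_band	>=85	61
age_band	Unknown	702
reporter	Consumer	306
reporter	Lawyer	1
reporter	Other health-professional	808
reporter	Pharmacist	345
reporter	Physician	1191
reporter	Unknown	292
sex	F	1121
sex	M	1443
sex	Unknown	379
year	2004	136
year	2005	132
year	2006	134
year	2007	120
year	2008	117
year	2009	137
year	2010	152
year	2011	129
year	2012	154
year	2013	156
year	2014	124
year	2015	174
year	2016	155
year	2017	183
year	2018	231
year	2019	262
year	2020	269
year	2021	171
year	Unknown	6
area	Africa	26
area	Asia	746
area	Europe	1203
area	North America	689
area	Oceania	39
area	South America	34
area	Unknown	206
drug	ketoconazole	188
drug	miconazole	48
drug	clotrimazole	10
drug	fluconazole	570
drug	voriconazole	955
drug	itraconazole	427
drug	isavuconazole	48
drug	posaconazole	216
drug	caspofungin	256
drug	micafungin	186
drug	anidulafungin	39
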