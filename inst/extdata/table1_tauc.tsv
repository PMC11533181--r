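surfactant	dispersant	guest	w0	tau_c_ps
AOT	isooctane		0.9	1276.9
AOT	isooctane		3.5	80.6
AOT	isooctane		6	16.1
AOT	isooctane		9.3	12.8
AOT	isooctane		12.8	9.0
AOT	isooctane		20.7	8.1
AOT	hexane		0.9	805.7
AOT	hexane		1.8	80.6
AOT	hexane		2.3	57.0
AOT	hexane		3.3	22.7
AOT	hexane		5.7	16.1
AOT	hexane		8.9	10.1
AOT	hexane		12.3	9.0
AOT	hexane		20.3	6.4
AOT	CCl4		0.9	805.7
AOT	CCl4		1.6	160.8
AOT	CCl4		2.7	71.8
AOT	CCl4		5.2	20.2
AOT	CCl4		7.4	12.8
Igepal	cyclohexane		1	25.5
Igepal	cyclohexane		1.8	22.7
Igepal	cyclohexane		3.3	10.1
Igepal	cyclohexane		5.4	9.0
Igepal	cyclohexane		7.8	8.1
Igepal	cyclohexane		14.7	5.7
CTAB	hexane		4	25.5
CTAB	hexane		9	22.7
CTAB	hexane		12.7	10.1
CTAB	hexane		15.6	9.0
CTAB	hexane		20.1	8.1
AOT	isooctane	glucose	1.9	160.8
AOT	isooctane	glucose	3.4	80.6
AOT	isooctane	glucose	5.7	32.1
AOT	isooctane	glucose	8.7	20.2
AOT	isooctane	glucose	11.7	12.8
AOT	isooctane	glucose	18	10.1
AOT	isooctane	PEG-200	1.9	202.4
AOT	isooctane	PEG-200	3.4	101.4
AOT	isooctane	PEG-200	5.5	80.6
AOT	isooctane	PEG-200	8	25.5
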