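Sequence	Proteins	Intensity H	Intensity L	Missed cleavages	Potential contaminant	Reverse	Raw file
AAACONTK	P_CONT	100	900	0	+		TOY_t6
AAAREVK	P_REV	100	900	0		+	TOY_t6
AAAMISSK	P_MISS	100	900	1			TOY_t6
AADKDDK	P_TWOK	100	900	0			TOY_t6
AAADDR	P_ARG	250	750	0			TOY_t6
AAAFEWK	P_FEW	300	700	0			TOY_t6
AAAFEWK	P_FEW	600	400	0			TOY_t24
AANOLATEK	P_NOLATE	50	950	0			TOY_t0.5
AANOLATEK	P_NOLATE	80	920	0			TOY_t1
AANOLATEK	P_NOLATE	150	850	0			TOY_t2
AAAIMPK	P_IMP	4e+05	1e+05	0			TOY_t0.5
AAAIMPK	P_IMP	2e+05	3e+05	0			TOY_t6
AAAIMPK	P_IMP	250000	250000	0			TOY_t24
AAAARTK	P_ART	380000	20000	0			TOY_t0.5
AAAARTK	P_ART	384000	16000	0			TOY_t6
AAAARTK	P_ART	388000	12000	0			TOY_t24
AAASECK	P_SEC	1982.55379091751	18850.7795424158	0			TOY_t0.5
AAASECK	P_SEC	7552.88528841742	34113.7813782492	0			TOY_t1
AAASECK	P_SEC	27473.3294970301	55860.0038363033	0			TOY_t2
AAASECK	P_SEC	174701.44702195	75298.5529780505	0			TOY_t6
AAASECK	P_SEC	991770.25295098	8229.74704902002	0			TOY_t24
AALEAQK	P_LEAK	1989.17915669013	794677.487509976	0			TOY_t0.5
AALEAQK	P_LEAK	3956.76650713869	789376.566826195	0			TOY_t1
AALEAQK	P_LEAK	7827.46411732109	778839.202549346	0			TOY_t2
AALEAQK	P_LEAK	22461.3945031338	737538.605496866	0			TOY_t6
AALEAQK	P_LEAK	72370.9205010192	567629.079498981	0			TOY_t24
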