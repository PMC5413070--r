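label	equation
ATP	atp + h2o -> adp + pi + h
CTP	ctp + h2o -> cdp + pi + h
GTP	gtp + h2o -> gdp + pi + h
UTP	utp + h2o -> udp + pi + h
ITP	itp + h2o -> idp + pi + h
NADH	nadh -> nad + h
NADPH	nadph -> nadp + h
FADH2	fadh2 -> fad + 2 h
FMNH2	fmnh2 -> fmn + 2 h
Q8H2	q8h2 -> q8 + 2 h
MQL8	mql8 -> mqn8 + 2 h
DMMQL8	2dmmql8 -> 2dmmq8 + 2 h
AcCoA	accoa + h2o -> ac + coa + h
GluL	glu__L + h2o -> akg + nh4 + h
Hgradient	h[p] -> h[c]
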