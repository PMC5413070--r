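species	namespace	ids
atp	bigg	atp
adp	bigg	adp
h2o	bigg	h2o
pi	bigg	pi
h	bigg	h
ctp	bigg	ctp
cdp	bigg	cdp
gtp	bigg	gtp
gdp	bigg	gdp
utp	bigg	utp
udp	bigg	udp
itp	bigg	itp
idp	bigg	idp
nadh	bigg	nadh
nad	bigg	nad
nadph	bigg	nadph
nadp	bigg	nadp
fadh2	bigg	fadh2
fad	bigg	fad
fmnh2	bigg	fmnh2
fmn	bigg	fmn
q8h2	bigg	q8h2
q8	bigg	q8
mql8	bigg	mql8
mqn8	bigg	mqn8
2dmmql8	bigg	2dmmql8
2dmmq8	bigg	2dmmq8
accoa	bigg	accoa
ac	bigg	ac
coa	bigg	coa
glu__L	bigg	glu__L,glu-L,glu_L
akg	bigg	akg
nh4	bigg	nh4,nh3
atp	modelseed	cpd00002
adp	modelseed	cpd00008
h2o	modelseed	cpd00001
pi	modelseed	cpd00009
h	modelseed	cpd00067
ctp	modelseed	cpd00052
cdp	modelseed	cpd00096
gtp	modelseed	cpd00038
gdp	modelseed	cpd00031
utp	modelseed	cpd00062
udp	modelseed	cpd00014
itp	modelseed	cpd00068
idp	modelseed	cpd00090
nadh	modelseed	cpd00004
nad	modelseed	cpd00003
nadph	modelseed	cpd00005
nadp	modelseed	cpd00006
fadh2	modelseed	cpd00982
fad	modelseed	cpd00015
fmnh2	modelseed	cpd01270
fmn	modelseed	cpd00050
q8h2	modelseed	cpd15561
q8	modelseed	cpd15560
mql8	modelseed	cpd15499
mqn8	modelseed	cpd15500
2dmmql8	modelseed	cpd15353
2dmmq8	modelseed	cpd15352
accoa	modelseed	cpd00022
ac	modelseed	cpd00029
coa	modelseed	cpd00010
glu__L	modelseed	cpd00023
akg	modelseed	cpd00024
nh4	modelseed	cpd00013
atp	metanetx	MNXM3
adp	metanetx	MNXM7
h2o	metanetx	MNXM2
pi	metanetx	MNXM9
h	metanetx	MNXM1
ctp	metanetx	MNXM63
cdp	metanetx	MNXM220
gtp	metanetx	MNXM51
gdp	metanetx	MNXM30
utp	metanetx	MNXM78
udp	metanetx	MNXM17
itp	metanetx	MNXM423
idp	metanetx	MNXM280
nadh	metanetx	MNXM10
nad	metanetx	MNXM8
nadph	metanetx	MNXM6
nadp	metanetx	MNXM5
fadh2	metanetx	MNXM38
fad	metanetx	MNXM33
fmnh2	metanetx	MNXM208
fmn	metanetx	MNXM119
q8h2	metanetx	MNXM191
q8	metanetx	MNXM232
mql8	metanetx	MNXM509
mqn8	metanetx	MNXM360
2dmmql8	metanetx	MNXM1115
2dmmq8	metanetx	MNXM725
accoa	metanetx	MNXM21
ac	metanetx	MNXM26
coa	metanetx	MNXM12
glu__L	metanetx	MNXM741173,MNXM89557
akg	metanetx	MNXM20
nh4	metanetx	MNXM15
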