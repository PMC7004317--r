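gene	role
ACE2	reported
ADD1	reported
ADRB2	reported
AGT	reported
AGTR1	reported
ANPEP	reported
ATP6AP2	reported
CYP17A1	reported
GNB3	reported
LNPEP	reported
MAS1	reported
MME	reported
NEDD4L	reported
PRKG1	reported
SGK1	reported
CLCNKB	unreported
CTSA	unreported
CYP3A5	unreported
ENPEP	unreported
SCNN1G	unreported
SLC24A3	unreported
THOP1	unreported
WNK1	unreported
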