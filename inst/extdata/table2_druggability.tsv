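protein	druggability_tier	target_type
ADK	Tier 2	Clinical trial Target
ADM	Tier 3A	Clinical trial Target
AGER	Tier 3A	Clinical trial Target
AIF1	/	Literature-reported target
APOE	Tier 3A	Clinical trial Target
BCL2	Tier 1	Successful Target
BOLA1	Tier 3A	/
BRD2	Tier 2	Clinical trial Target
BTN1A1	Tier 3A	/
BTN3A1	Tier 3B	/
CD244	Tier 3A	/
CILP2	Tier 3A	/
CLUL1	Tier 3B	Literature-reported target
CNTN1	Tier 3A	/
CXCL1	Tier 3B	Literature-reported target
DEFB104A	Tier 3B	/
DEFB104B	Tier 3B	/
DKKL1	Tier 3A	/
EPHB6	Tier 1	Literature-reported target
ERP29	Tier 3A	/
F2	Tier 1	Successful Target
FABP4	Tier 2	/
FCRL1	Tier 3A	/
HAPLN4	Tier 3A	/
HLA-DQA2	Tier 3A	/
HSPA1A	Tier 2	Clinical trial Target
HSPA1B	Tier 2	Clinical trial Target
HYOU1	Tier 3B	/
IFNGR2	Tier 1	Successful Target
IGFBP1	Tier 2	Discontinued Target
INSL4	Tier 3A	/
ITGB7	Tier 1	Successful Target
KEL	Tier 3B	/
KLB	/	Clinical trial Target
LGALS7	Tier 3B	/
LGALS7B	Tier 3B	/
LTBR	Tier 1	Clinical trial Target
MGP	Tier 3B	/
NFKB1	Tier 1	Successful Target
NOTCH3	Tier 3B	Clinical trial Target
PARP1	Tier 1	Successful Target
PPIE	Tier 2	/
PSMB9	Tier 3B	Literature-reported target
QPCT	Tier 2	Clinical trial Target
RPN1	Tier 3A	/
RSPO3	Tier 3A	Clinical trial Target
SECTM1	Tier 3B	/
SFTA2	Tier 3A	/
SIGLEC12	Tier 3B	/
ST3GAL1	Tier 3B	/
TEX101	Tier 3B	/
TNF	Tier 1	Clinical trial Target
TNFRSF14	Tier 3A	Literature-reported target
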