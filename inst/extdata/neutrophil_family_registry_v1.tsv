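gene_symbol	family
MPO	azurophilic_granule
ELANE	azurophilic_granule
CTSG	azurophilic_granule
PRTN3	azurophilic_granule
AZU1	azurophilic_granule
BPI	azurophilic_granule
DEFA1	azurophilic_granule
DEFA4	azurophilic_granule
CTSC	azurophilic_granule
RNASE3	azurophilic_granule
LTF	specific_granule
LCN2	specific_granule
CAMP	specific_granule
MMP25	specific_granule
CYBB	specific_granule
OLFM4	specific_granule
HP	specific_granule
PGLYRP1	specific_granule
FCN1	ficolin_granule
CHI3L1	ficolin_granule
GSN	ficolin_granule
B2M	ficolin_granule
ALPL	secretory_vesicle
CD177	secretory_vesicle
MGAM	secretory_vesicle
CR1	secretory_vesicle
CEACAM8	secretory_vesicle
H2AC1	histones
H2BC1	histones
H3C1	histones
H4C1	histones
H2AC4	histones
H2BC14	histones
H3C2	histones
H4C2	histones
H1-2	histones
H1-4	histones
LMNB1	nuclear_membrane
LMNB2	nuclear_membrane
LBR	nuclear_membrane
NUP62	nuclear_membrane
NUP98	nuclear_membrane
RANBP2	nuclear_membrane
SELL	cell_membrane
CD44	cell_membrane
CD55	cell_membrane
SLC44A2	cell_membrane
CEACAM1	cell_membrane
ICAM3	cell_membrane
RPS2	ribosomal_40S
RPS3	ribosomal_40S
RPS4	ribosomal_40S
RPS5	ribosomal_40S
RPS6	ribosomal_40S
RPS7	ribosomal_40S
RPS8	ribosomal_40S
RPS9	ribosomal_40S
RPS10	ribosomal_40S
RPS11	ribosomal_40S
RPS12	ribosomal_40S
RPS13	ribosomal_40S
RPS14	ribosomal_40S
RPS15	ribosomal_40S
RPS16	ribosomal_40S
RPS17	ribosomal_40S
RPS18	ribosomal_40S
RPS19	ribosomal_40S
RPS20	ribosomal_40S
RPS21	ribosomal_40S
RPS23	ribosomal_40S
RPS24	ribosomal_40S
RPS25	ribosomal_40S
RPL4	ribosomal_60S
RPL7	ribosomal_60S
RPL15	ribosomal_60S
RPL3	ribosomal_60S
RPL5	ribosomal_60S
RPL6	ribosomal_60S
RPL8	ribosomal_60S
RPL9	ribosomal_60S
RPL10	ribosomal_60S
RPL11	ribosomal_60S
RPL12	ribosomal_60S
RPL13	ribosomal_60S
RPL14	ribosomal_60S
NDUFA2	electron_transport_chain
NDUFB4	electron_transport_chain
NDUFS1	electron_transport_chain
SDHA	electron_transport_chain
SDHB	electron_transport_chain
UQCRC1	electron_transport_chain
UQCRC2	electron_transport_chain
COX4I1	electron_transport_chain
COX5A	electron_transport_chain
ATP5F1A	electron_transport_chain
ATP5F1B	electron_transport_chain
TOMM5	mitochondrial_membrane
IMMT	mitochondrial_membrane
TOMM20	mitochondrial_membrane
TOMM22	mitochondrial_membrane
TIMM23	mitochondrial_membrane
VDAC1	mitochondrial_membrane
VDAC2	mitochondrial_membrane
PDHB	mitochondrial_metabolism
IDH3A	mitochondrial_metabolism
ACAT1	mitochondrial_metabolism
CS	mitochondrial_metabolism
FH	mitochondrial_metabolism
MDH2	mitochondrial_metabolism
SUCLA2	mitochondrial_metabolism
OGDH	mitochondrial_metabolism
C3	complement_coagulation
C5	complement_coagulation
CFB	complement_coagulation
FGA	complement_coagulation
FGB	complement_coagulation
FGG	complement_coagulation
F2	complement_coagulation
F9	complement_coagulation
PLG	complement_coagulation
CLU	complement_coagulation
SERPINC1	complement_coagulation
CTSD	lysosome
LAMP1	lysosome
LAMP2	lysosome
SCARB2	lysosome
HEXB	lysosome
GUSB	lysosome
GLB1	lysosome
PSMA1	proteasome_20S
PSMA2	proteasome_20S
PSMA3	proteasome_20S
PSMA4	proteasome_20S
PSMA5	proteasome_20S
PSMA6	proteasome_20S
PSMA7	proteasome_20S
PSMB1	proteasome_20S
PSMB2	proteasome_20S
PSMB3	proteasome_20S
PSMB4	proteasome_20S
PSMB5	proteasome_20S
PSMB6	proteasome_20S
PSMB7	proteasome_20S
IGHG1	immunoglobulins
IGHG3	immunoglobulins
IGHA1	immunoglobulins
IGKC	immunoglobulins
IGLC2	immunoglobulins
DSP	desmosome
DSG1	desmosome
DSC1	desmosome
JUP	desmosome
PKP1	desmosome
ACTB	cytoskeleton
ACTN1	cytoskeleton
VIM	cytoskeleton
TUBB	cytoskeleton
CORO1A	cytoskeleton
MSN	cytoskeleton
EZR	cytoskeleton
TLN1	cytoskeleton
FLNA	cytoskeleton
PYGL	glycolysis_glycogenolysis_ppp
SLC2A3	glycolysis_glycogenolysis_ppp
PFKL	glycolysis_glycogenolysis_ppp
PKM	glycolysis_glycogenolysis_ppp
GAPDH	glycolysis_glycogenolysis_ppp
ALDOA	glycolysis_glycogenolysis_ppp
ENO1	glycolysis_glycogenolysis_ppp
G6PD	glycolysis_glycogenolysis_ppp
PGD	glycolysis_glycogenolysis_ppp
TALDO1	glycolysis_glycogenolysis_ppp
PCNA	dna_replication
CEBPE	dna_replication
MCM2	dna_replication
MCM3	dna_replication
MCM4	dna_replication
MCM5	dna_replication
MCM6	dna_replication
MCM7	dna_replication
POLA1	dna_replication
LIG1	dna_replication
RFC1	dna_replication
MMP8	maturity_markers
MMP9	maturity_markers
S100A8	maturity_markers
S100A9	maturity_markers
ITGAM	maturity_markers
ITGB2	maturity_markers
FCGR3B	maturity_markers
ARG1	ia_markers
S100A7	ia_markers
ECM1	ia_markers
S100A10	ia_markers
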