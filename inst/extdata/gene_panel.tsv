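gene	gene_name	function
ABCB1	ATP-binding cassette subfamily B member 1	Xenobiotic transport
ABCG2	ATP-binding cassette subfamily G member 2	Xenobiotic transport
ADAM23	ADAM metallopeptidase domain 23	Proteolysis
AKT1	AKT serine/threonine kinase 1	Signal transduction (AKT/PI3K signaling)
APC	Adenomatosis polyposis coli	WNT signaling; cell adhesion; apoptosis; cell cycle; DNA repair
AR	Androgen receptor	Steroid receptor-mediated signaling; transcription factor
ATM	ATM serine/threonine kinase	DNA damage and repair
BCL2	BCL2 apoptosis regulator	Hedgehog signaling; cell adhesion; apoptosis; cell cycle
BIRC5	Baculoviral IAP repeat-containing 5	Notch signaling
BRCA1	Breast cancer 1	DNA repair; steroid receptor-mediated signaling
BRCA2	Breast cancer 2	DNA damage and repair
CCNA1	Cyclin A1	Cell cycle
CCND1	Cyclin D1	Cell cycle; DNA repair; hedgehog and WNT signaling
CCND2	Cyclin D2	Cell cycle
CCNE1	Cyclin E1	Cell cycle; steroid receptor-mediated signaling
CDH13	Cadherin 13	Cell adhesion; angiogenesis
CDK2	Cyclin-dependent kinase 2	Cell cycle
CDKN1A	Cyclin-dependent kinase inhibitor 1A	Cell cycle; DNA repair; apoptosis
CDKN1C	Cyclin-dependent kinase inhibitor 1C	Cell cycle
CDKN2A	Cyclin-dependent kinase inhibitor 2A	Cell cycle; apoptosis; cell adhesion
CST6	Cystatin E/M	Proteases
CTNNB1	Catenin beta 1	Steroid receptor signaling; EMT; angiogenesis; cell adhesion
CTSD	Cathepsin D	Proteases
EGF	Epidermal growth factor	Angiogenesis
ERBB2	Erb-b2 receptor tyrosine kinase 2	AKT/PI3K signaling; angiogenesis; cell adhesion
ESR1	Estrogen receptor 1	Steroid receptor-mediated signaling; transcription factor
ESR2	Estrogen receptor 2	Steroid receptor-mediated signaling; transcription factor
FOXA1	Forkhead box A1	Transcription factor
GATA3	GATA-binding protein 3	Transcription factor
HIC1	HIC ZBTB transcriptional repressor 1	Transcription factor
ID1	Inhibitor of DNA binding 1	Angiogenesis; metastasis to lung; classification marker
IGF1	Insulin-like growth factor 1	Steroid receptor and AKT/PI3K signaling
IGF1R	Insulin-like growth factor 1 receptor	AKT/PI3K signaling
IGFBP3	Insulin-like growth factor-binding protein 3	Glucocorticoid signaling
IL6	Interleukin 6	Angiogenesis; apoptosis
JUN	Jun proto-oncogene	Angiogenesis; apoptosis; cell cycle; transcription factor
KRT19	Keratin 19	Steroid receptor-mediated signaling
MAPK1	Mitogen-activated protein kinase 1	MAP kinase signaling; DNA damage and repair
MAPK3	Mitogen-activated protein kinase 3	MAP kinase-mediated signaling
MAPK8	Mitogen-activated protein kinase 8	MAP kinase-mediated signaling
MGMT	O-6-methylguanine-DNA methyltransferase	DNA damage and repair
MKI67	Marker of proliferation Ki-67	Cell cycle
MLH1	MutL homolog 1	DNA damage and repair
MMP2	Matrix metallopeptidase 2	Proteases; metastasis to lung; classification marker
MMP9	Matrix metallopeptidase 9	Proteases
MYC	V-myc avian myelocytomatosis viral oncogene homolog	Cell cycle; transcription factor
NME1	NME/NM23 nucleoside diphosphate kinase 1	Glucocorticoid signaling; apoptosis
NOTCH1	Notch 1	Notch signaling; angiogenesis
NR3C1	Nuclear receptor subfamily 3 group C member 1	Glucocorticoid signaling; transcription factor
PGR	Progesterone receptor	Steroid receptor-mediated signaling; transcription factor
PLAU	Plasminogen activator, urokinase	Angiogenesis; proteases
PRDM2	PR/SET domain 2	Transcription factor
PTEN	Phosphatase and tensin homolog	AKT/PI3K signaling; angiogenesis; cell adhesion; cell cycle
PYCARD	PYD and CARD domain-containing	Proteases
RARB	Retinoic acid receptor beta	Apoptosis; transcription factor
RASSF1	Ras-association domain family member 1	Cell cycle
RB1	RB transcriptional corepressor 1	Steroid receptor signaling; cell cycle; transcription factor
SERPINE1	Serpin family E member 1	Angiogenesis
SFN	Stratifin	Apoptosis; cell cycle; DNA damage and repair
SFRP1	Secreted frizzled-related protein 1	WNT signaling; apoptosis
SLIT2	Slit guidance ligand 2	Angiogenesis
THBS1	Thrombospondin 1	Angiogenesis; cell adhesion
TP53	Tumor protein p53	Apoptosis; cell cycle; DNA repair; transcription factor
TP73	Tumor protein p73	Apoptosis; DNA repair; transcription factor; MAP kinase signaling
VEGFA	Vascular endothelial growth factor A	Angiogenesis
XBP1	X-box binding protein 1	Transcription factor
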