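symbol	comment
CBX5	Cooperates with Myb and Hmgb3 to form ESC-like myeloid leukemic stem cells
GATA3	Transcription factor, poor prognosis marker in endometrial and breast cancers
MYCL1	L-Myc oncogene
HOXB7	Promotes EMT, the angiogenic switch, tumor progression and lung metastasis in breast cancer
HOXC4/HOXC6	Over-expressed in primary prostate tumors and lymph node metastases
RIT1	Ras-like transforming oncogene
IGFBP5	Pro-fibrotic factor in lung, induces EMT; prognostic value in breast cancer
NRG1	EGFR/ERBB ligand, induces lung branching morphogenesis and epithelial proliferation
FGFBP1	Mobilizes stored FGFs to induce the angiogenic switch in tumors
FHL1	Tumor suppressor gene
PTGIS	Over-expression prevents lung carcinogenesis in mice; anti-proliferative
CASP1	Apoptosis inducer
CASP4	Apoptosis inducer
CLU	Absence in NSCLC associated with shorter survival
TGFBR3	Suppresses NSCLC cell invasion and tumorigenicity
TNFSF10	TRAIL, apoptosis inducer
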