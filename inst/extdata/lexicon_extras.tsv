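# surface	tag
# Gene symbols (canonical + common synonym spellings)
ARID1A	gene
ATM	gene
ATR	gene
BRCA1	gene
BRCA2	gene
CHK2	gene
CHEK2	gene
PALB2	gene
BARD1	gene
BRIP1	gene
RAD51B	gene
RAD51C	gene
RAD51D	gene
RAD54L	gene
CDK12	gene
FANCA	gene
NBN	gene
TP53	gene
p53	gene
KRAS	gene
NRAS	gene
BRAF	gene
EGFR	gene
ALK	gene
ROS1	gene
MET	gene
RET	gene
HER2	gene
ERBB2	gene
VEGF	gene
PIK3CA	gene
PTEN	gene
AKT1	gene
FGFR2	gene
FGFR3	gene
IDH1	gene
IDH2	gene
NTRK1	gene
MSH2	gene
MLH1	gene
# Organ mentions for organ+histology combination
lung	organ
liver	organ
breast	organ
ovary	organ
ovarian	organ
pancreas	organ
pancreatic	organ
prostate	organ
colon	organ
rectum	organ
kidney	organ
renal	organ
skin	organ
brain	organ
stomach	organ
gastric	organ
bladder	organ
esophagus	organ
# Anatomic sites for lesion measurability
lymph node	site
lymph nodes	site
axillary lymph node	site
mediastinal lymph node	site
supraclavicular lymph node	site
cervical lymph node	site
vertebra	site
L4 vertebra	site
T8 vertebra	site
iliac bone	site
bone	site
rib	site
femur	site
sternum	site
adrenal gland	site
spleen	site
# Metastatic status cues
metastatic	Metastasis
metastasis	Metastasis
metastases	Metastasis
secondary malignant neoplasm	Secondary_Malignant
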