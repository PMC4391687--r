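gene	transcript	syndrome_association
APC	NM_000038.5	familial adenomatous polyposis / attenuated FAP
ATM	NM_000051.3	hereditary breast and pancreatic cancer risk
BARD1	NM_000465.3	hereditary breast cancer risk
BMPR1A	NM_004329.2	juvenile polyposis syndrome
BRCA1	NM_007294.3	hereditary breast and ovarian cancer syndrome
BRCA2	NM_000059.3	hereditary breast and ovarian cancer syndrome
BRIP1	NM_032043.2	hereditary breast and ovarian cancer risk
CDH1	NM_004360.3	hereditary diffuse gastric cancer syndrome
CDK4	NM_000075.3	melanoma cancer syndrome
CHEK2	NM_007194.3	hereditary breast, colorectal and prostate cancer risk
EPCAM	NM_002354.2	Lynch syndrome (large rearrangements of the last two exons only)
MLH1	NM_000249.3	Lynch syndrome
MSH2	NM_000251.2	Lynch syndrome
MSH6	NM_000179.2	Lynch syndrome
MUTYH (alpha5)	NM_001128425.1	MUTYH-associated colon cancer risk / polyposis
MUTYH (alpha3)	NM_001048171.1	MUTYH-associated colon cancer risk / polyposis
NBN	NM_002485.4	hereditary breast and prostate cancer risk
P14ARF	NM_058195.3	melanoma-pancreatic cancer syndrome (CDKN2A locus)
P16	NM_000077.4	melanoma-pancreatic cancer syndrome (CDKN2A locus)
PALB2	NM_024675.3	hereditary breast and pancreatic cancer risk
PMS2	NM_000535.5	Lynch syndrome
PTEN	NM_000314.4	PTEN hamartoma tumor syndrome
RAD51C	NM_058216.2	hereditary breast and ovarian cancer risk
RAD51D	NM_002878.3	hereditary ovarian cancer risk
SMAD4	NM_005359.5	juvenile polyposis syndrome
STK11	NM_000455.4	Peutz-Jeghers syndrome
TP53	NM_000546.5	Li-Fraumeni syndrome
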