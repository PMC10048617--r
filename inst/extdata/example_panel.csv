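locus,dye,repeat_bp,base_bp,simple,allele_min,allele_max
D3S1358,Blue,4,66,FALSE,12,19
vWA,Blue,4,100,FALSE,11,21
D16S539,Blue,4,212,TRUE,5,15
CSF1PO,Blue,4,257,TRUE,6,15
TPOX,Blue,4,310,TRUE,6,13
D8S1179,Green,4,72,FALSE,8,18
D21S11,Green,4,107,FALSE,24,35
D18S51,Green,4,196,FALSE,9,26
D2S441,Green,4,330,FALSE,9,16
D19S433,Yellow,4,55,FALSE,9,17
TH01,Yellow,4,136,FALSE,5,10
FGA,Yellow,4,148,FALSE,17,30
D22S1045,Red,3,58,FALSE,8,19
D5S818,Red,4,100,TRUE,7,16
D13S317,Red,4,160,TRUE,8,15
D7S820,Red,4,222,TRUE,6,14
SE33,Purple,4,122,FALSE,12,32
D10S1248,Purple,4,40,TRUE,8,18
D1S1656,Purple,4,115,FALSE,9,19
D12S391,Purple,4,200,FALSE,15,26
D2S1338,Purple,4,300,FALSE,15,27
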