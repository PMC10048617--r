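Sample Name,Marker,Allele 1,Allele 2,Allele 3,Allele 4,Allele 5,Allele 6,Allele 7,Allele 8,Allele 9,Height 1,Height 2,Height 3,Height 4,Height 5,Height 6,Height 7,Height 8,Height 9,Size 1,Size 2,Size 3,Size 4,Size 5,Size 6,Size 7,Size 8,Size 9
example-2cell,CSF1PO,12,13,NA,NA,NA,NA,NA,NA,NA,64.61161768944649,434.8383753007337,NA,NA,NA,NA,NA,NA,NA,305,309,NA,NA,NA,NA,NA,NA,NA
example-2cell,D10S1248,9,13,13.5,14,NA,NA,NA,NA,NA,123.83104762250595,206.47389457827217,115.64012983738013,2266.127516647139,NA,NA,NA,NA,NA,76,92,94,96,NA,NA,NA,NA,NA
example-2cell,D12S391,20,21,21.5,22,23,NA,NA,NA,NA,82.30488627395451,241.9755808029119,175.73486503097587,3000.7380656425116,132.62912352464355,NA,NA,NA,NA,280,284,286,288,292,NA,NA,NA,NA
example-2cell,D13S317,8,9,NA,NA,NA,NA,NA,NA,NA,67.03643196679171,1295.91287429888,NA,NA,NA,NA,NA,NA,NA,192,196,NA,NA,NA,NA,NA,NA,NA
example-2cell,D16S539,6,6.5,7.5,8,8.5,9,10,NA,NA,174.23316727153454,55.727070273366365,222.38248529013157,6025.196102905733,115.20419956556348,212.72389620363595,674.1722120642662,NA,NA,236,238,242,244,246,248,252,NA,NA
example-2cell,D18S51,19,20,NA,NA,NA,NA,NA,NA,NA,158.06466572457575,1179.3349802693865,NA,NA,NA,NA,NA,NA,NA,272,276,NA,NA,NA,NA,NA,NA,NA
example-2cell,D19S433,14,14.5,15,15.5,16,16.5,17,NA,NA,185.34050135765312,103.80937090262879,1050.211705892467,392.0297255369205,7462.984775020622,127.07080983867145,367.0581370438856,NA,NA,111,113,115,117,119,121,123,NA,NA
example-2cell,D1S1656,12,17,NA,NA,NA,NA,NA,NA,NA,112.20678758712437,292.60832548489645,NA,NA,NA,NA,NA,NA,NA,163,183,NA,NA,NA,NA,NA,NA,NA
example-2cell,D21S11,23.5,24,25,29,29.5,30,30.5,31,NA,214.9132486600762,3655.958178689195,141.3195337250491,350.37718169498703,249.2673384879328,4347.114594136192,96.32000192931768,191.06315159602826,NA,201,203,207,223,225,227,229,231,NA
example-2cell,D22S1045,9,10,11,11.5,12,12.5,13,NA,NA,718.3558667176015,392.9283676239511,1340.1945531113386,1270.308930457393,24852.420901894948,849.2334835077004,997.7926145692262,NA,NA,85,88,91,92.5,94,95.5,97,NA,NA
example-2cell,D2S1338,16,25,NA,NA,NA,NA,NA,NA,NA,242.88262703837336,92.91748000881182,NA,NA,NA,NA,NA,NA,NA,364,400,NA,NA,NA,NA,NA,NA,NA
example-2cell,D2S441,14,15,15.5,16,16.5,17,NA,NA,NA,165.91873905164283,1651.875479266766,285.8791922070804,8913.666223895516,130.454006218809,195.13404744483293,NA,NA,NA,386,390,392,394,396,398,NA,NA,NA
example-2cell,D3S1358,12,16,17,18,NA,NA,NA,NA,NA,145.62530622343425,279.7645416799382,1849.583019647238,63.4668796504222,NA,NA,NA,NA,NA,114,130,134,138,NA,NA,NA,NA,NA
example-2cell,D5S818,12,13,16,NA,NA,NA,NA,NA,NA,71.19459608815588,804.4604054161391,255.53913777681794,NA,NA,NA,NA,NA,NA,148,152,164,NA,NA,NA,NA,NA,NA
example-2cell,D7S820,10,10.5,11,11.5,12,13,14,NA,NA,199.33846039172897,73.00790758724196,601.8359979759514,294.44306264740607,6327.926531527554,245.71587206734682,390.37549100457113,NA,NA,262,264,266,268,270,274,278,NA,NA
example-2cell,D8S1179,9,9.5,10,11,NA,NA,NA,NA,NA,119.56459333080117,87.84130469513144,2813.515712781169,134.38825034063782,NA,NA,NA,NA,NA,108,110,112,116,NA,NA,NA,NA,NA
example-2cell,FGA,25,26,26.5,27,28,NA,NA,NA,NA,60.86197672672258,526.66391658388,206.7837404666148,3005.8120516548897,122.33118976733898,NA,NA,NA,NA,248,252,254,256,260,NA,NA,NA,NA
example-2cell,SE33,12,NA,NA,NA,NA,NA,NA,NA,NA,421.98889150259913,NA,NA,NA,NA,NA,NA,NA,NA,170,NA,NA,NA,NA,NA,NA,NA,NA
example-2cell,TH01,5,5.5,6,6.5,7,7.5,8,9,NA,457.2728507343941,120.2384316275938,1549.3082955128818,1187.4754156333943,16106.867958494175,163.81631592945058,781.9049284365126,420.36701680471714,NA,156,158,160,162,164,166,168,172,NA
example-2cell,TPOX,10,12,12.5,13,14,NA,NA,NA,NA,69.1686837966711,213.18037736663493,84.52127626822916,1488.20144829458,57.182728824988345,NA,NA,NA,NA,350,358,360,362,366,NA,NA,NA,NA
example-2cell,vWA,20,21,NA,NA,NA,NA,NA,NA,NA,65.05802250844323,458.3746495496606,NA,NA,NA,NA,NA,NA,NA,180,184,NA,NA,NA,NA,NA,NA,NA
example-minimix,CSF1PO,4,5,5.5,6,7,9,10,13,NA,95.32289186064818,54.60213781417479,156.90711752743985,2593.9306508703103,93.6978903645901,88.13014793028594,878.1193244265805,339.9157531548451,NA,273,277,279,281,285,293,297,309,NA
example-minimix,D10S1248,9,12,13,13.5,14,14.5,15,NA,NA,277.393705964539,75.99104111449545,360.11977507827964,127.72995829524903,3284.06659868112,71.84414308619365,122.42049546810037,NA,NA,76,88,92,94,96,98,100,NA,NA
example-minimix,D12S391,16,17,21,21.5,22,23,NA,NA,NA,86.86013729093942,1173.7489859878847,259.1105166015561,126.93964628028561,2101.0158727991775,82.10523861298084,NA,NA,NA,264,268,284,286,288,292,NA,NA,NA
example-minimix,D13S317,7.5,8,8.5,9,10,NA,NA,NA,NA,91.40409050685359,273.4383550210504,195.7522535043255,5727.644455749441,178.50980655934933,NA,NA,NA,NA,190,192,194,196,200,NA,NA,NA,NA
example-minimix,D16S539,7.5,8,8.5,9,9.5,10,NA,NA,NA,95.45393357830915,1548.5382453136044,63.03277311042035,123.34767887211589,61.75277470366177,984.8636436109806,NA,NA,NA,242,244,246,248,250,252,NA,NA,NA
example-minimix,D18S51,11,16.5,17,NA,NA,NA,NA,NA,NA,2053.670937989254,152.74546412240926,1949.732242276493,NA,NA,NA,NA,NA,NA,240,262,264,NA,NA,NA,NA,NA,NA
example-minimix,D19S433,10,15,16,NA,NA,NA,NA,NA,NA,90.93108342246065,49.08684193002781,683.394437434526,NA,NA,NA,NA,NA,NA,95,115,119,NA,NA,NA,NA,NA,NA
example-minimix,D1S1656,12,17,18,NA,NA,NA,NA,NA,NA,134.3669063747154,131.836011163524,283.9327874402489,NA,NA,NA,NA,NA,NA,163,183,187,NA,NA,NA,NA,NA,NA
example-minimix,D21S11,24,25,NA,NA,NA,NA,NA,NA,NA,313.8531924275994,685.8540183833107,NA,NA,NA,NA,NA,NA,NA,203,207,NA,NA,NA,NA,NA,NA,NA
example-minimix,D22S1045,9,12,19,NA,NA,NA,NA,NA,NA,1004.0145227624893,151.53316484384524,116.4807563226711,NA,NA,NA,NA,NA,NA,85,94,115,NA,NA,NA,NA,NA,NA
example-minimix,D2S1338,16,16.5,17,18,24,25,NA,NA,NA,289.8975032942361,129.6083728897169,1913.4694491385353,74.9569240684045,76.21461052588782,323.1831960061976,NA,NA,NA,364,366,368,372,396,400,NA,NA,NA
example-minimix,D2S441,14,15,15.5,16,NA,NA,NA,NA,NA,496.1770036443303,195.66936357930373,95.24945704127477,1504.2860397548861,NA,NA,NA,NA,NA,386,390,392,394,NA,NA,NA,NA,NA
example-minimix,D3S1358,11.5,12,13,NA,NA,NA,NA,NA,NA,163.90273149852183,3435.125292007085,114.74363346610606,NA,NA,NA,NA,NA,NA,112,114,118,NA,NA,NA,NA,NA,NA
example-minimix,D5S818,9.5,10,10.5,11,12,13,NA,NA,NA,73.34679714492489,188.5336402032098,108.09391207880476,2458.3256577709267,167.16484988113618,131.0422488066214,NA,NA,NA,138,140,142,144,148,152,NA,NA,NA
example-minimix,D7S820,11,12,13,14,NA,NA,NA,NA,NA,177.3698667791586,1315.7749297594678,108.08011360349073,237.6769359235705,NA,NA,NA,NA,NA,266,270,274,278,NA,NA,NA,NA,NA
example-minimix,D8S1179,9,10,13,14,14.5,15,16,NA,NA,96.75352924424308,616.7567626766813,105.72273357137803,482.84851662783376,177.45983056568997,4769.303155385378,256.3840081581589,NA,NA,108,112,124,128,130,132,136,NA,NA
example-minimix,FGA,22,26,27,NA,NA,NA,NA,NA,NA,406.57137602399763,90.68936407137372,786.528796216611,NA,NA,NA,NA,NA,NA,236,252,256,NA,NA,NA,NA,NA,NA
example-minimix,SE33,14,14.5,15.5,16,16.5,17,19,NA,NA,202.8143005502971,91.75015026285689,240.9045157786964,6352.946116523954,80.66339578900833,473.18038615416157,115.68898704483792,NA,NA,178,180,184,186,188,190,198,NA,NA
example-minimix,TH01,6,7,8,9,NA,NA,NA,NA,NA,48.0767845863695,746.7977150389671,699.5210379152089,512.3144868736958,NA,NA,NA,NA,NA,160,164,168,172,NA,NA,NA,NA,NA
example-minimix,TPOX,9,10,12,13,NA,NA,NA,NA,NA,133.45206100851806,104.87235976097297,121.59118441445735,593.8473995138431,NA,NA,NA,NA,NA,346,350,358,362,NA,NA,NA,NA,NA
example-minimix,vWA,16,16.5,17,17.5,18,18.5,19,20,21,192.24476594186285,137.03211934038333,826.4865393087737,447.44500613674836,6641.132250079132,83.7767946409354,373.3548333799112,524.083909134123,53.76166179144751,164,166,168,170,172,174,176,180,184
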