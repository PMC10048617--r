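locus,allele,freq
CSF1PO,6,0.147778
CSF1PO,7,0.033644
CSF1PO,8,0.011819
CSF1PO,9,0.046541
CSF1PO,10,0.26962
CSF1PO,11,0.071421
CSF1PO,12,0.125522
CSF1PO,13,0.052522
CSF1PO,14,0.051361
CSF1PO,15,0.189771
D10S1248,8,0.014269
D10S1248,9,0.167622
D10S1248,10,0.079036
D10S1248,11,0.070748
D10S1248,12,0.103795
D10S1248,13,0.095156
D10S1248,14,0.14434
D10S1248,15,0.069356
D10S1248,16,0.167895
D10S1248,17,0.04081
D10S1248,18,0.046973
D12S391,15,0.049528
D12S391,16,0.050795
D12S391,17,0.183411
D12S391,18,0.036168
D12S391,19,0.034068
D12S391,20,0.03675
D12S391,21,0.082817
D12S391,22,0.097111
D12S391,23,0.126219
D12S391,24,0.110863
D12S391,25,0.08115
D12S391,26,0.111121
D13S317,8,0.039809
D13S317,9,0.468759
D13S317,10,0.071147
D13S317,11,0.039729
D13S317,12,0.054692
D13S317,13,0.018315
D13S317,14,0.232988
D13S317,15,0.074561
D16S539,5,0.111419
D16S539,6,0.067605
D16S539,7,0.068327
D16S539,8,0.087569
D16S539,9,0.12637
D16S539,10,0.118269
D16S539,11,0.083584
D16S539,12,0.051525
D16S539,13,0.109959
D16S539,14,0.099295
D16S539,15,0.076078
D18S51,9,0.035179
D18S51,10,0.098143
D18S51,11,0.019139
D18S51,12,0.05622
D18S51,13,0.111343
D18S51,14,0.02379
D18S51,15,0.027361
D18S51,16,0.054239
D18S51,17,0.033035
D18S51,18,0.109364
D18S51,19,0.074232
D18S51,20,0.069275
D18S51,21,0.044595
D18S51,22,0.004708
D18S51,23,0.054619
D18S51,24,0.032064
D18S51,25,0.059417
D18S51,26,0.093278
D19S433,9,0.045809
D19S433,10,0.076299
D19S433,11,0.118262
D19S433,12,0.191141
D19S433,13,0.185668
D19S433,14,0.091296
D19S433,15,0.137814
D19S433,16,0.124495
D19S433,17,0.029216
D1S1656,9,0.098677
D1S1656,10,0.061735
D1S1656,11,0.158802
D1S1656,12,0.067994
D1S1656,13,0.022516
D1S1656,14,0.087108
D1S1656,15,0.093264
D1S1656,16,0.07746
D1S1656,17,0.06823
D1S1656,18,0.139886
D1S1656,19,0.12433
D21S11,24,0.170143
D21S11,25,0.130197
D21S11,26,0.024189
D21S11,27,0.052694
D21S11,28,0.102633
D21S11,29,0.111281
D21S11,30,0.07621
D21S11,31,0.058319
D21S11,32,0.10221
D21S11,33,0.047036
D21S11,34,0.040914
D21S11,35,0.084175
D22S1045,8,0.034664
D22S1045,9,0.15414
D22S1045,10,0.067925
D22S1045,11,0.099231
D22S1045,12,0.051276
D22S1045,13,0.03668
D22S1045,14,0.092611
D22S1045,15,0.129465
D22S1045,16,0.057943
D22S1045,17,0.057932
D22S1045,18,0.01571
D22S1045,19,0.202422
D2S1338,15,0.005126
D2S1338,16,0.208071
D2S1338,17,0.060315
D2S1338,18,0.096968
D2S1338,19,0.031595
D2S1338,20,0.091427
D2S1338,21,0.107747
D2S1338,22,0.032627
D2S1338,23,0.090401
D2S1338,24,0.043684
D2S1338,25,0.125903
D2S1338,26,0.078032
D2S1338,27,0.028102
D2S441,9,0.137826
D2S441,10,0.097228
D2S441,11,0.015208
D2S441,12,0.080654
D2S441,13,0.16782
D2S441,14,0.173397
D2S441,15,0.125234
D2S441,16,0.202634
D3S1358,12,0.239315
D3S1358,13,0.016739
D3S1358,14,0.113559
D3S1358,15,0.202901
D3S1358,16,0.058744
D3S1358,17,0.109061
D3S1358,18,0.058032
D3S1358,19,0.20165
D5S818,7,0.136191
D5S818,8,0.072987
D5S818,9,0.016696
D5S818,10,0.020119
D5S818,11,0.209441
D5S818,12,0.023152
D5S818,13,0.16832
D5S818,14,0.075441
D5S818,15,0.223796
D5S818,16,0.053858
D7S820,6,0.013402
D7S820,7,0.313994
D7S820,8,0.018965
D7S820,9,0.13316
D7S820,10,0.033453
D7S820,11,0.080859
D7S820,12,0.110353
D7S820,13,0.043427
D7S820,14,0.252388
D8S1179,8,0.08867
D8S1179,9,0.068304
D8S1179,10,0.112866
D8S1179,11,0.092324
D8S1179,12,0.115688
D8S1179,13,0.122676
D8S1179,14,0.088435
D8S1179,15,0.074027
D8S1179,16,0.020777
D8S1179,17,0.081787
D8S1179,18,0.134446
FGA,17,0.089275
FGA,18,0.041089
FGA,19,0.062516
FGA,20,0.051778
FGA,21,0.048281
FGA,22,0.081542
FGA,23,0.097564
FGA,24,0.036312
FGA,25,0.061829
FGA,26,0.037588
FGA,27,0.18955
FGA,28,0.034763
FGA,29,0.113956
FGA,30,0.053957
SE33,12,0.11115
SE33,13,0.019488
SE33,14,0.033069
SE33,15,0.015505
SE33,16,0.090025
SE33,17,0.033484
SE33,18,0.020039
SE33,19,0.178152
SE33,20,0.009732
SE33,21,0.039875
SE33,22,0.016759
SE33,23,0.01855
SE33,24,0.071868
SE33,25,0.066646
SE33,26,0.050097
SE33,27,0.019727
SE33,28,0.04892
SE33,29,0.047724
SE33,30,0.050855
SE33,31,0.028342
SE33,32,0.029992
TH01,5,0.171301
TH01,6,0.087712
TH01,7,0.107289
TH01,8,0.143368
TH01,9,0.246324
TH01,10,0.244007
TPOX,6,0.157248
TPOX,7,0.134114
TPOX,8,0.012138
TPOX,9,0.120616
TPOX,10,0.16531
TPOX,11,0.182052
TPOX,12,0.088613
TPOX,13,0.139909
vWA,11,0.170616
vWA,12,0.076887
vWA,13,0.021866
vWA,14,0.108993
vWA,15,0.095899
vWA,16,0.049525
vWA,17,0.089925
vWA,18,0.127425
vWA,19,0.01018
vWA,20,0.165593
vWA,21,0.08309
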