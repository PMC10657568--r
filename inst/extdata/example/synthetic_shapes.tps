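LM=33
-0.939788 0.035965
-1.032938 -0.103962
-0.867929 0.119427
-0.967987 -0.268570
-0.593526 0.042945
-0.844443 -0.321366
-0.518419 -0.048876
-0.504036 -0.470295
-0.378325 -0.280329
-0.393025 -0.400247
-0.579423 -0.342919
-0.526075 -0.246109
-0.633728 -0.235410
-1.032429 -0.204856
-1.024525 -0.236840
-0.994356 -0.277253
-0.965504 -0.314310
-0.921493 -0.346981
-0.896236 -0.380689
-0.841140 -0.409232
-0.793310 -0.436104
-0.722480 -0.456782
-0.660930 -0.482980
-0.739879 0.089978
-0.677249 0.079900
-0.602014 0.053400
-0.542575 0.038925
-0.478687 0.018951
-0.429406 0.000179
-0.425126 -0.031507
-0.383617 -0.063252
-0.366684 -0.101553
-0.372725 -0.138215
ID=sp1_st1_i1_r1
LM=33
-0.401134 -0.542412
-0.525223 -0.463134
-0.320337 -0.600758
-0.667234 -0.527878
-0.378610 -0.848475
-0.715288 -0.641306
-0.457801 -0.915432
-0.836522 -0.946687
-0.658438 -1.050497
-0.765800 -1.046164
-0.721305 -0.875876
-0.632750 -0.917812
-0.626284 -0.822852
-0.613471 -0.467181
-0.648599 -0.475192
-0.679042 -0.505756
-0.710428 -0.533938
-0.733735 -0.573350
-0.767748 -0.596418
-0.788540 -0.644950
-0.811426 -0.690087
-0.828149 -0.754310
-0.852171 -0.809089
-0.342449 -0.717919
-0.348521 -0.775241
-0.373812 -0.844407
-0.380024 -0.893770
-0.397401 -0.954917
-0.408575 -0.992590
-0.435684 -1.001629
-0.466156 -1.037441
-0.500329 -1.051361
-0.530855 -1.052405
ID=sp1_st1_i1_r2
LM=33
-0.252286 -0.164391
-0.145831 -0.238496
-0.310468 -0.112941
-0.018541 -0.193964
-0.243622 0.093682
0.024193 -0.095158
-0.184940 0.170795
0.119777 0.147644
-0.019454 0.269691
0.081327 0.244748
0.032600 0.097027
-0.040933 0.156922
-0.038855 0.070108
-0.059418 -0.233690
-0.044470 -0.223970
-0.028143 -0.199631
0.014741 -0.184661
0.020429 -0.169256
0.048543 -0.121614
0.086453 -0.090468
0.098555 -0.053376
0.124586 0.003270
0.138844 0.043788
-0.296578 -0.011513
-0.279400 0.041485
-0.274741 0.086055
-0.254396 0.143743
-0.235267 0.170738
-0.207068 0.219156
-0.202291 0.230136
-0.172939 0.267024
-0.150387 0.261246
-0.122024 0.272010
ID=sp1_st1_i2_r1
LM=33
0.055542 -0.200852
0.143945 -0.145671
-0.003198 -0.225075
0.155994 -0.036119
-0.133013 -0.106209
0.095512 0.032791
-0.171985 -0.038044
-0.051048 0.181611
-0.188624 0.119112
-0.135167 0.187679
-0.041593 0.099685
-0.113114 0.067512
-0.046230 0.041407
0.170620 -0.082299
0.167602 -0.065818
0.156867 -0.045009
0.159521 -0.007297
0.150680 0.003363
0.124431 0.037947
0.114134 0.077401
0.090563 0.096346
0.056058 0.137001
0.029841 0.158800
-0.075087 -0.180643
-0.106632 -0.150476
-0.136615 -0.132823
-0.173636 -0.099053
-0.188138 -0.074451
-0.212558 -0.034689
-0.219859 -0.030220
-0.235508 0.004962
-0.227035 0.019979
-0.223300 0.042075
ID=sp1_st1_i2_r2
LM=33
-0.352214 0.610962
-0.223160 0.632042
-0.430605 0.599008
-0.190567 0.756078
-0.541063 0.767950
-0.211444 0.850208
-0.545610 0.876222
-0.337984 1.108490
-0.503184 1.067823
-0.428011 1.122458
-0.351484 1.000372
-0.451564 0.985307
-0.381824 0.916472
-0.177694 0.688916
-0.165600 0.727505
-0.163429 0.749639
-0.160927 0.771322
-0.164602 0.824281
-0.165524 0.848917
-0.184003 0.889098
-0.192140 0.936161
-0.221673 0.986284
-0.224729 1.036358
-0.506898 0.670387
-0.532242 0.710448
-0.549538 0.762898
-0.577111 0.790640
-0.590810 0.848898
-0.616462 0.886904
-0.601086 0.925895
-0.589548 0.942067
-0.604864 0.969694
-0.588091 0.996392
ID=sp1_st1_i3_r1
LM=33
-0.046611 0.651418
0.055958 0.652968
-0.112420 0.650271
0.097295 0.752590
-0.183368 0.793533
0.090813 0.827894
-0.177655 0.887507
0.013721 1.047144
-0.121098 1.034770
-0.055254 1.072139
-0.006971 0.964840
-0.087931 0.962466
-0.039537 0.897917
0.101573 0.697550
0.112963 0.726517
0.119330 0.742718
0.123091 0.758422
0.127449 0.800968
0.128866 0.823921
0.118945 0.856837
0.116022 0.894780
0.097419 0.940830
0.099372 0.981071
-0.166105 0.715983
-0.181982 0.748571
-0.191722 0.791199
-0.209417 0.820853
-0.218024 0.867349
-0.233354 0.900973
-0.218050 0.930908
-0.203043 0.942525
-0.215083 0.966577
-0.197523 0.984922
ID=sp1_st1_i3_r2
LM=33
0.903689 0.971506
0.911339 1.036005
0.883096 0.868983
0.750649 1.066089
0.745562 0.833720
0.649193 1.065882
0.669493 0.851901
0.518850 1.150063
0.479143 0.960550
0.468899 1.093654
0.556405 1.061045
0.551714 0.978229
0.604309 0.978904
0.837876 1.064366
0.802893 1.069383
0.762103 1.076705
0.723169 1.093815
0.685521 1.114394
0.654272 1.126757
0.623018 1.127545
0.614282 1.138066
0.586387 1.166852
0.577646 1.174456
0.809239 0.817252
0.785548 0.824335
0.762471 0.825214
0.726047 0.827250
0.699914 0.832011
0.656239 0.833715
0.628124 0.837022
0.590638 0.835750
0.569653 0.837738
0.533462 0.854564
ID=sp2_st1_i1_r1
LM=33
-0.427938 -0.308048
-0.324649 -0.301037
-0.587768 -0.297263
-0.319983 -0.051597
-0.673465 -0.093549
-0.343595 0.105236
-0.664444 0.022312
-0.246964 0.322624
-0.541733 0.338190
-0.345282 0.386943
-0.372635 0.245287
-0.503086 0.231611
-0.486899 0.153924
-0.302587 -0.179947
-0.303265 -0.127342
-0.296762 -0.059237
-0.283809 0.003007
-0.260629 0.062010
-0.253629 0.117333
-0.255388 0.161659
-0.245767 0.178880
-0.208673 0.223120
-0.195903 0.243075
-0.684057 -0.196963
-0.682457 -0.160302
-0.681644 -0.124736
-0.691524 -0.070421
-0.685599 -0.029536
-0.694171 0.041916
-0.701115 0.078601
-0.712689 0.135453
-0.706892 0.172854
-0.697232 0.232636
ID=sp2_st1_i1_r2
LM=33
0.092790 0.851129
-0.019478 0.939319
0.213250 0.684825
-0.266113 0.709190
0.116191 0.419494
-0.394662 0.564923
-0.021043 0.317187
-0.669391 0.427863
-0.420831 0.151030
-0.641068 0.290094
-0.478807 0.401805
-0.342340 0.264864
-0.297245 0.371961
-0.158858 0.853631
-0.196659 0.798651
-0.284395 0.772493
-0.334084 0.711039
-0.410037 0.637970
-0.457254 0.623238
-0.529938 0.591096
-0.549532 0.587739
-0.587589 0.588163
-0.652958 0.572532
0.229564 0.534873
0.194008 0.466106
0.138179 0.419178
0.089858 0.377810
0.046477 0.326388
0.019730 0.289439
-0.022441 0.215400
-0.076195 0.184095
-0.116594 0.145537
-0.171735 0.120471
ID=sp2_st1_i2_r1
LM=33
-0.073428 0.933257
-0.177001 0.867752
0.105966 0.981420
-0.065352 0.598551
0.283280 0.822611
0.013050 0.450516
0.334615 0.678850
0.041087 0.186553
0.342644 0.304190
0.166250 0.168065
0.122821 0.330354
0.275232 0.403455
0.200903 0.469717
-0.146961 0.730582
-0.114195 0.683900
-0.117996 0.600153
-0.085323 0.537652
-0.046767 0.459281
-0.050026 0.418154
-0.048375 0.348100
-0.050481 0.328510
-0.062986 0.298207
-0.064820 0.246187
0.231078 0.947732
0.275467 0.899032
0.296476 0.841840
0.313503 0.788762
0.344978 0.740820
0.364289 0.706483
0.413365 0.645274
0.422542 0.594198
0.441923 0.548887
0.449049 0.494617
ID=sp2_st1_i2_r2
LM=33
0.290004 0.311384
0.197307 0.296145
0.457091 0.321234
0.202895 0.023827
0.550393 0.111830
0.206022 -0.119499
0.560650 -0.027112
0.142843 -0.358581
0.430274 -0.353797
0.253294 -0.403412
0.264585 -0.251581
0.407286 -0.230427
0.375743 -0.166962
0.163831 0.195573
0.161170 0.109419
0.151256 0.045787
0.154024 -0.026739
0.131008 -0.085397
0.135989 -0.128653
0.128899 -0.184711
0.110262 -0.199463
0.099052 -0.245189
0.087560 -0.275858
0.562381 0.231618
0.584416 0.178113
0.573912 0.124382
0.582137 0.070195
0.581006 0.031478
0.590397 -0.006613
0.600085 -0.083915
0.601168 -0.132098
0.613135 -0.164801
0.601972 -0.224611
ID=sp2_st1_i3_r1
LM=33
-0.823421 -0.725401
-0.895335 -0.805081
-0.701691 -0.595502
-0.690913 -1.030356
-0.465492 -0.699193
-0.586992 -1.141410
-0.360169 -0.810107
-0.465082 -1.380893
-0.231478 -1.170819
-0.337681 -1.338288
-0.440972 -1.205725
-0.335916 -1.087397
-0.410594 -1.058471
-0.845617 -0.915901
-0.785488 -0.985971
-0.750266 -1.044053
-0.696625 -1.097569
-0.672060 -1.165668
-0.632428 -1.196233
-0.603244 -1.249650
-0.607287 -1.276112
-0.586290 -1.321378
-0.571599 -1.357671
-0.553618 -0.591640
-0.489263 -0.617089
-0.462190 -0.672792
-0.415553 -0.710255
-0.385545 -0.745355
-0.352267 -0.769666
-0.287458 -0.828130
-0.252080 -0.868692
-0.219514 -0.883175
-0.183145 -0.941578
ID=sp2_st1_i3_r2
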