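# label x y z
E001 -0.737361 0.675483 0.004505
E002 0.087418 -0.996080 0.013514
E003 0.608285 0.793399 0.022523
E004 -0.984224 -0.174095 0.031532
E005 0.843062 -0.536287 0.040541
E006 -0.259285 0.964529 0.049550
E007 -0.460116 -0.885926 0.058559
E008 0.937175 0.342255 0.067568
E009 -0.921631 0.380436 0.076577
E010 0.422291 -0.902411 0.085586
E011 0.297942 0.949886 0.094595
E012 -0.860555 -0.498709 0.103604
E013 0.970463 -0.213354 0.112613
E014 -0.570860 0.811990 0.121622
E015 -0.127409 -0.983210 0.130631
E016 0.757157 0.638133 0.139640
E017 -0.988046 0.040859 0.148649
E018 0.699965 -0.696558 0.157658
E019 -0.045545 0.984961 0.166667
E020 -0.630745 -0.755843 0.175676
E021 0.974021 0.131053 0.184685
E022 -0.805313 0.560316 0.193694
E023 0.214925 -0.955363 0.202703
E024 0.485911 0.847979 0.211712
E025 -0.929197 -0.296439 0.220721
E026 0.883512 -0.408205 0.229730
E027 -0.374898 0.895799 0.238739
E028 -0.327901 -0.911648 0.247748
E029 0.855514 0.449634 0.256757
E030 -0.932195 0.245724 0.265766
E031 0.520020 -0.808751 0.274775
E032 0.162413 0.945034 0.283784
E033 -0.755975 -0.585469 0.292793
E034 0.950116 -0.078715 0.301802
E035 -0.645446 0.697708 0.310811
E036 0.004622 -0.947467 0.319820
E037 0.634521 0.699467 0.328829
E038 -0.937188 -0.086858 0.337838
E039 0.747110 -0.567030 0.346847
E040 -0.167267 0.919450 0.355856
E041 -0.495888 -0.788016 0.364865
E042 0.894496 0.245144 0.373874
E043 -0.821889 0.421780 0.382883
E044 0.319811 -0.862636 0.391892
E045 0.345417 0.848508 0.400901
E046 -0.824248 -0.390627 0.409910
E047 0.867719 -0.267527 0.418919
E048 -0.456988 0.779769 0.427928
E049 -0.188851 -0.879444 0.436937
E050 0.729695 0.518341 0.445946
E051 -0.883678 0.110131 0.454955
E052 0.574184 -0.674574 0.463964
E053 0.032109 0.880492 0.472973
E054 -0.615004 -0.624071 0.481982
E055 0.870028 0.044485 0.490991
E056 -0.667619 0.551620 0.500000
E057 0.118940 -0.852504 0.509009
E058 0.485098 0.704512 0.518018
E059 -0.828207 -0.190568 0.527027
E060 0.734502 -0.416140 0.536036
E061 -0.258715 0.797491 0.545045
E062 -0.345470 -0.757413 0.554054
E063 0.760779 0.322761 0.563063
E064 -0.773143 0.273831 0.572072
E065 0.382136 -0.718552 0.581081
E066 0.201972 0.781666 0.590090
E067 -0.671349 -0.436315 0.599099
E068 0.783031 -0.130642 0.608108
E069 -0.484833 0.619761 0.617117
E070 -0.060586 -0.777364 0.626126
E071 0.564427 0.527281 0.635135
E072 -0.764868 -0.007463 0.644144
E073 0.563319 -0.506027 0.653153
E074 -0.072793 0.745817 0.662162
E075 -0.445276 -0.592671 0.671171
E076 0.720559 0.134720 0.680180
E077 -0.615135 0.382920 0.689189
E078 0.192588 -0.689514 0.698198
E079 0.319727 0.630581 0.707207
E080 -0.653165 -0.245784 0.716216
E081 0.638956 -0.256484 0.725225
E082 -0.293733 0.612063 0.734234
E083 -0.193990 -0.640279 0.743243
E084 0.566816 0.335911 0.752252
E085 -0.634649 0.133048 0.761261
E086 0.371843 -0.518090 0.770270
E087 0.074467 0.622237 0.779279
E088 -0.466602 -0.401104 0.788288
E089 0.603286 -0.019054 0.797297
E090 -0.423322 0.413121 0.806306
E091 0.032387 -0.578111 0.815315
E092 0.358459 0.438174 0.824324
E093 -0.547089 -0.079052 0.833333
E094 0.445378 -0.303477 0.842342
E095 -0.120127 0.510657 0.851351
E096 -0.249080 -0.444679 0.860360
E097 0.469298 0.154779 0.869369
E098 -0.435828 0.196227 0.878378
E099 0.182124 -0.423526 0.887387
E100 0.145944 0.418538 0.896396
E101 -0.373861 -0.201170 0.905405
E102 0.392397 -0.099351 0.914414
E103 -0.210704 0.320770 0.923423
E104 -0.057726 -0.356704 0.932432
E105 0.264553 0.209045 0.941441
E106 -0.310050 0.022644 0.950450
E107 0.193406 -0.205017 0.959459
E108 -0.003646 0.249109 0.968468
E109 -0.140263 -0.157684 0.977477
E110 0.162988 0.016711 0.986486
E111 -0.076077 0.056578 0.995495
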