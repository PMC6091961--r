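# label x y z
E01 -0.737344 0.675468 0.008197
E02 0.087399 -0.995870 0.024590
E03 0.607928 0.792934 0.040984
E04 -0.983091 -0.173895 0.057377
E05 0.841456 -0.535266 0.073770
E06 -0.258547 0.961782 0.090164
E07 -0.458283 -0.882396 0.106557
E08 0.932194 0.340436 0.122951
E09 -0.915328 0.377834 0.139344
E10 0.418674 -0.894683 0.155738
E11 0.294817 0.939922 0.172131
E12 -0.849697 -0.492417 0.188525
E13 0.955950 -0.210163 0.204918
E14 -0.560868 0.797777 0.221311
E15 -0.124827 -0.963283 0.237705
E16 0.739552 0.623295 0.254098
E17 -0.961900 0.039778 0.270492
E18 0.679034 -0.675729 0.286885
E19 -0.044016 0.951885 0.303279
E20 -0.607090 -0.727497 0.319672
E21 0.933427 0.125591 0.336066
E22 -0.768182 0.534481 0.352459
E23 0.204005 -0.906824 0.368852
E24 0.458805 0.800677 0.385246
E25 -0.872474 -0.278343 0.401639
E26 0.824666 -0.381017 0.418033
E27 -0.347728 0.830878 0.434426
E28 -0.302108 -0.839936 0.450820
E29 0.782636 0.411331 0.467213
E30 -0.846375 0.223102 0.483607
E31 0.468379 -0.728437 0.500000
E32 0.145046 0.843978 0.516393
E33 -0.669064 -0.518161 0.532787
E34 0.832851 -0.069000 0.549180
E35 -0.560035 0.605382 0.565574
E36 0.003967 -0.813203 0.581967
E37 0.538332 0.593433 0.598361
E38 -0.785353 -0.072786 0.614754
E39 0.617862 -0.468935 0.631148
E40 -0.136391 0.749725 0.647541
E41 -0.398278 -0.632903 0.663934
E42 0.706844 0.193717 0.680328
E43 -0.638209 0.327518 0.696721
E44 0.243696 -0.657328 0.713115
E45 0.257887 0.633492 0.729508
E46 -0.601886 -0.285245 0.745902
E47 0.618501 -0.190690 0.762295
E48 -0.317233 0.541302 0.778689
E49 -0.127337 -0.592984 0.795082
E50 0.476419 0.338426 0.811475
E51 -0.556616 0.069370 0.827869
E52 0.347374 -0.408109 0.844262
E53 0.018556 0.508849 0.860656
E54 -0.337200 -0.342171 0.877049
E55 0.448591 0.022937 0.893443
E56 -0.319899 0.264316 0.909836
E57 0.052088 -0.373344 0.926230
E58 0.189338 0.274978 0.942623
E59 -0.276135 -0.063538 0.959016
E60 0.191761 -0.108644 0.975410
E61 -0.039428 0.121539 0.991803
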