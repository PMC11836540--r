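region,year,age_lo,asfr
region_a,2001,15,0.08550911104885836
region_a,2001,20,0.17590789144703906
region_a,2001,25,0.1679810610698659
region_a,2001,30,0.10607391545522302
region_a,2001,35,0.05276904504930054
region_a,2001,40,0.02275854957866328
region_a,2001,45,0.009000426351049844
region_a,2100,15,0.006013225208110931
region_a,2100,20,0.04645319120727265
region_a,2100,25,0.09312557291891624
region_a,2100,30,0.08808780955560788
region_a,2100,35,0.05310055195770157
region_a,2100,40,0.024109805852094848
region_a,2100,45,0.009109843300295909
region_b,2001,15,0.07341436741044549
region_b,2001,20,0.18222560930359927
region_b,2001,25,0.1925410315676099
region_b,2001,30,0.12796865117316097
region_b,2001,35,0.06494613370545735
region_b,2001,40,0.02799422049551062
region_b,2001,45,0.010909986344216374
region_b,2100,15,0.0037203606318208502
region_b,2100,20,0.0402911837177859
region_b,2100,25,0.09654657565429339
region_b,2100,30,0.09958766672937411
region_b,2100,35,0.06183013079654093
region_b,2100,40,0.027849141475546728
region_b,2100,45,0.010174940994638105
region_c,2001,15,0.07914006007458126
region_c,2001,20,0.17850191324945153
region_c,2001,25,0.19164138706918127
region_c,2001,30,0.13741168700462386
region_c,2001,35,0.07786495792584794
region_c,2001,40,0.038245755836387875
region_c,2001,45,0.017194238839926258
region_c,2100,15,0.007754303659101807
region_c,2100,20,0.051673476248290794
region_c,2100,25,0.09969825128170681
region_c,2100,30,0.09641222030299806
region_c,2100,35,0.06158511848553416
region_c,2100,40,0.03029644364609537
region_c,2100,45,0.012580186376273011
region_d,2001,15,0.08325600511463113
region_d,2001,20,0.21822524275823468
region_d,2001,25,0.22800148079975302
region_d,2001,30,0.14466136067951313
region_d,2001,35,0.06869016444457782
region_d,2001,40,0.027373127627114087
region_d,2001,45,0.00979261857617612
region_d,2100,15,0.005003461079624053
region_d,2100,20,0.04516792517162081
region_d,2100,25,0.10254210977262032
region_d,2100,30,0.10757677573184428
region_d,2100,35,0.07086359454566214
region_d,2100,40,0.034770474848928326
region_d,2100,45,0.014075658849700056
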