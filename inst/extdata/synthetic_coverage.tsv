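individual	chrom	start	end	depth
ind0001	chrA	0	100000	18.653
ind0001	chrA	100000	200000	18.5937
ind0001	chrA	200000	300000	19.2676
ind0001	chrA	300000	400000	20.983
ind0001	chrA	400000	500000	16.8712
ind0001	chrA	500000	600000	19.1945
ind0001	chrA	600000	700000	20.1636
ind0001	chrA	700000	800000	20.3963
ind0001	chrA	800000	900000	20.9489
ind0001	chrA	900000	1000000	20.8247
ind0001	chrA	1000000	1100000	20.4327
ind0001	chrA	1100000	1200000	20.4733
ind0001	chrA	1200000	1300000	21.1214
ind0001	chrA	1300000	1400000	21.7385
ind0001	chrA	1400000	1500000	18.7942
ind0001	chrA	1500000	1600000	20.1341
ind0001	chrA	1600000	1700000	19.1974
ind0001	chrA	1700000	1800000	18.8101
ind0001	chrA	1800000	1900000	20.111
ind0001	chrA	1900000	2000000	20.5713
ind0001	chrB	0	100000	19.048
ind0001	chrB	100000	200000	20.0145
ind0001	chrB	200000	300000	18.5552
ind0001	chrB	300000	400000	19.7931
ind0001	chrB	400000	500000	19.4312
ind0001	chrB	500000	600000	18.7264
ind0001	chrB	600000	700000	20.1464
ind0001	chrB	700000	800000	20.814
ind0001	chrB	800000	900000	19.5105
ind0001	chrB	900000	1000000	18.545
ind0001	chrB	1000000	1100000	21.0501
ind0001	chrB	1100000	1200000	21.099
ind0001	chrB	1200000	1300000	21.2457
ind0001	chrB	1300000	1400000	19.4772
ind0001	chrB	1400000	1500000	20.7085
ind0002	chrA	0	100000	18.8085
ind0002	chrA	100000	200000	21.8095
ind0002	chrA	200000	300000	21.383
ind0002	chrA	300000	400000	19.9137
ind0002	chrA	400000	500000	19.8866
ind0002	chrA	500000	600000	20.2914
ind0002	chrA	600000	700000	19.6339
ind0002	chrA	700000	800000	20.0232
ind0002	chrA	800000	900000	20.0344
ind0002	chrA	900000	1000000	20.3075
ind0002	chrA	1000000	1100000	17.7636
ind0002	chrA	1100000	1200000	20.2636
ind0002	chrA	1200000	1300000	20.4953
ind0002	chrA	1300000	1400000	17.9352
ind0002	chrA	1400000	1500000	20.4314
ind0002	chrA	1500000	1600000	20.1552
ind0002	chrA	1600000	1700000	19.4147
ind0002	chrA	1700000	1800000	19.1669
ind0002	chrA	1800000	1900000	21.0048
ind0002	chrA	1900000	2000000	19.2349
ind0002	chrB	0	100000	21.7437
ind0002	chrB	100000	200000	20.2789
ind0002	chrB	200000	300000	20.9754
ind0002	chrB	300000	400000	19.8679
ind0002	chrB	400000	500000	20.9652
ind0002	chrB	500000	600000	20.3045
ind0002	chrB	600000	700000	19.112
ind0002	chrB	700000	800000	19.8339
ind0002	chrB	800000	900000	20.7873
ind0002	chrB	900000	1000000	20.338
ind0002	chrB	1000000	1100000	21.8251
ind0002	chrB	1100000	1200000	17.7057
ind0002	chrB	1200000	1300000	19.8505
ind0002	chrB	1300000	1400000	20.7446
ind0002	chrB	1400000	1500000	20.6181
ind0003	chrA	0	100000	21.336
ind0003	chrA	100000	200000	19.8922
ind0003	chrA	200000	300000	21.2551
ind0003	chrA	300000	400000	19.7364
ind0003	chrA	400000	500000	20.2335
ind0003	chrA	500000	600000	20.1258
ind0003	chrA	600000	700000	19.4187
ind0003	chrA	700000	800000	20.4783
ind0003	chrA	800000	900000	20.3776
ind0003	chrA	900000	1000000	20.0081
ind0003	chrA	1000000	1100000	21.7271
ind0003	chrA	1100000	1200000	20.1813
ind0003	chrA	1200000	1300000	20.3924
ind0003	chrA	1300000	1400000	20.5161
ind0003	chrA	1400000	1500000	21.3966
ind0003	chrA	1500000	1600000	19.4138
ind0003	chrA	1600000	1700000	19.8928
ind0003	chrA	1700000	1800000	20.9739
ind0003	chrA	1800000	1900000	20.2971
ind0003	chrA	1900000	2000000	21.8398
ind0003	chrB	0	100000	21.0254
ind0003	chrB	100000	200000	19.6159
ind0003	chrB	200000	300000	19.7903
ind0003	chrB	300000	400000	20.2378
ind0003	chrB	400000	500000	19.224
ind0003	chrB	500000	600000	20.5464
ind0003	chrB	600000	700000	18.4868
ind0003	chrB	700000	800000	18.5479
ind0003	chrB	800000	900000	19.5017
ind0003	chrB	900000	1000000	19.8511
ind0003	chrB	1000000	1100000	19.8674
ind0003	chrB	1100000	1200000	19.6258
ind0003	chrB	1200000	1300000	19.1511
ind0003	chrB	1300000	1400000	20.2203
ind0003	chrB	1400000	1500000	19.195
ind0004	chrA	0	100000	20.5406
ind0004	chrA	100000	200000	21.2902
ind0004	chrA	200000	300000	20.2299
ind0004	chrA	300000	400000	20.7162
ind0004	chrA	400000	500000	21.6444
ind0004	chrA	500000	600000	20.539
ind0004	chrA	600000	700000	19.5929
ind0004	chrA	700000	800000	19.5691
ind0004	chrA	800000	900000	19.4861
ind0004	chrA	900000	1000000	20.5649
ind0004	chrA	1000000	1100000	20.624
ind0004	chrA	1100000	1200000	17.8436
ind0004	chrA	1200000	1300000	19.5889
ind0004	chrA	1300000	1400000	20.0585
ind0004	chrA	1400000	1500000	20.1908
ind0004	chrA	1500000	1600000	18.9575
ind0004	chrA	1600000	1700000	18.8141
ind0004	chrA	1700000	1800000	21.3049
ind0004	chrA	1800000	1900000	20.5523
ind0004	chrA	1900000	2000000	19.444
ind0004	chrB	0	100000	19.4679
ind0004	chrB	100000	200000	19.6231
ind0004	chrB	200000	300000	20.2307
ind0004	chrB	300000	400000	20.9573
ind0004	chrB	400000	500000	20.715
ind0004	chrB	500000	600000	18.7905
ind0004	chrB	600000	700000	19.1925
ind0004	chrB	700000	800000	20.4503
ind0004	chrB	800000	900000	19.5725
ind0004	chrB	900000	1000000	19.0115
ind0004	chrB	1000000	1100000	20.3121
ind0004	chrB	1100000	1200000	19.7147
ind0004	chrB	1200000	1300000	18.7968
ind0004	chrB	1300000	1400000	20.0581
ind0004	chrB	1400000	1500000	19.2569
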