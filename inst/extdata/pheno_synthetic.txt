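line_id	trial_id	GY
L0001	T01	1.14733200011767
L0001	T02	-1.29491925887882
L0001	T03	0.28336953273805
L0002	T01	-1.92234151825176
L0002	T02	-1.27922178997755
L0002	T03	NA
L0003	T01	0.103337307397015
L0003	T02	1.00835810299092
L0003	T03	-0.221175134534774
L0004	T02	0.5857049477519
L0004	T03	-0.871276345863093
L0005	T02	0.840991635346186
L0005	T01	2.15553820486435
L0006	T01	0.437904076581701
L0006	T03	0.517203193731411
L0007	T02	-0.0378165661455997
L0007	T01	1.58189323396424
L0008	T03	-0.285292236744012
L0008	T01	0.409619504683222
L0009	T01	1.25681800225046
L0009	T03	-0.370573816875461
L0010	T02	-0.36519701485745
L0010	T01	-1.21061153290627
L0011	T01	0.431204617632432
L0011	T02	-0.285304918311682
L0012	T01	-0.198034817073343
L0012	T03	0.409477583195085
L0013	T03	3.35856130553178
L0013	T01	1.81725899821433
L0014	T01	-1.22977862150303
L0014	T03	-1.91446719969404
L0015	T01	-0.377445287901065
L0015	T02	1.97883631448239
L0016	T03	-0.289554638126413
L0016	T01	-0.101375856403733
L0017	T03	-0.947714792045008
L0017	T02	0.362937749448741
L0018	T02	-1.51917599696258
L0018	T03	-0.921724513494662
L0019	T03	1.31220660696506
L0019	T01	1.58158743943187
L0020	T03	-0.264891870152629
L0020	T01	-1.2839028547183
L0021	T03	2.04067658175761
L0021	T02	0.829904316271581
L0022	T03	-1.50500385201668
L0022	T02	-2.03518859062738
L0023	T01	-1.11416440016374
L0023	T03	-2.3385087947962
L0024	T01	-1.1116896837184
L0024	T02	-2.58884780836407
L0025	T02	1.82233536508904
L0025	T03	2.05729970973834
L0026	T02	-1.6741932416256
L0026	T03	-1.8250650646051
L0027	T03	2.15048002667327
L0027	T01	-0.134575143965827
L0028	T03	-0.198742982795641
L0028	T01	0.370456232745183
L0029	T03	0.999824448064775
L0029	T01	0.781049282558633
L0030	T02	0.258468744720114
L0030	T01	1.9131912499959
L0031	T02	0.825007699606974
L0031	T03	0.399145076250185
L0032	T02	-3.21365776128656
L0032	T01	-1.92852001254739
L0033	T01	1.87933234251868
L0033	T03	0.585784628406767
L0034	T01	NA
L0034	T03	1.18781978926109
L0035	T02	0.696242962561387
L0035	T03	0.474214973043141
L0036	T03	-2.51187387747516
L0036	T02	-0.031188435961004
L0037	T03	-1.25656587155851
L0037	T02	-0.93748573908886
L0038	T01	-0.36186950613362
L0038	T02	NA
L0039	T02	-1.89005872188462
L0039	T03	1.77282874407669
L0040	T01	-0.845713331838141
L0040	T03	1.19974056434964
L0041	T01	0.161309228900084
L0041	T03	NA
L0042	T01	-2.38621476000509
L0042	T03	-2.01292186299948
L0043	T03	-0.991750004516898
L0043	T01	-1.35468600968511
L0044	T01	-0.0220489178588479
L0044	T03	-1.49394214784162
L0045	T03	0.905052259849815
L0045	T01	0.867281158926268
L0046	T02	0.837905446859723
L0046	T01	0.233209796890994
L0047	T03	-1.51314105157013
L0047	T01	-0.550958259027596
L0048	T01	-0.769194248684551
L0048	T03	-0.520355536331324
L0049	T01	2.30025212522488
L0049	T02	1.25122546343529
L0050	T02	-0.105417375665841
L0050	T03	1.28054022974336
L0051	T02	0.339252785841856
L0051	T01	0.951961879168756
L0052	T02	-0.661641893084362
L0052	T01	-1.28718681936581
L0053	T01	0.696669888208308
L0053	T02	0.424802170485804
L0054	T03	0.616112712699027
L0054	T01	0.206638960119543
L0055	T01	0.290942149496769
L0055	T03	2.25537673162707
L0056	T02	0.216182068544087
L0056	T01	1.03084603842779
L0057	T01	0.512136408506202
L0057	T03	1.9522067971328
L0058	T02	-0.968059888826524
L0058	T03	-0.963089939712714
L0059	T02	0.572436427524508
L0059	T01	0.787635550884418
L0060	T03	2.04737014602506
L0060	T01	2.88849340497523
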