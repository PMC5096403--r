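pair	ks_yn	mya_yn	ks_ng	mya_ng	ks_ml	mya_ml
A.sativa_3-A.sativa_2	0.0135	1.1	0.0137	1.1	0.0130	1.1
A.sativa_1-A.sativa_2	0.1019	8.4	0.0964	7.9	0.1003	8.2
A.sativa_1-A.sativa_3	0.1056	8.7	0.1002	8.2	0.1038	8.5
Wheat-Barley	0.1479	12.1	0.1547	12.7	0.1523	12.5
Barley-A.sativa_2	0.3040	24.9	0.2940	24.1	0.2981	24.4
Barley-A.sativa_3	0.3034	24.9	0.2944	24.1	0.2983	24.5
Barley-A.sativa_1	0.2855	23.4	0.2811	23.0	0.2849	23.4
Wheat-A.sativa_2	0.3228	26.5	0.3173	26.0	0.3109	25.5
Wheat-A.sativa_3	0.3221	26.4	0.3173	26.0	0.3112	25.5
Wheat-A.sativa_1	0.3148	25.8	0.3096	25.4	0.3098	25.4
Brachy-A.sativa_2	0.3561	29.2	0.3620	29.7	0.3747	30.7
Brachy-A.sativa_3	0.3657	30.0	0.3711	30.4	0.3815	31.3
Brachy-A.sativa_1	0.3667	30.1	0.3684	30.2	0.3802	31.2
Brachy-Barley	0.3760	30.8	0.3787	31.0	0.3789	31.1
Brachy-Wheat	0.3805	31.2	0.3893	31.9	0.3866	31.7
Rice-A.sativa_2	0.5859	48.0	0.6530	53.5	0.5964	48.9
Rice-A.sativa_3	0.5851	48.0	0.6498	53.3	0.5943	48.7
Rice-A.sativa_1	0.5745	47.1	0.6397	52.4	0.5914	48.5
Rice-Barley	0.6205	50.9	0.7048	57.8	0.6615	54.2
Rice-Wheat	0.5742	47.1	0.6465	53.0	0.5951	48.8
Rice-Brachy	0.5905	48.4	0.6352	52.1	0.6071	49.8
Maize-A.sativa_2	0.7074	58.0	0.7137	58.5	0.6862	56.2
Maize-A.sativa_3	0.6939	56.9	0.7085	58.1	0.6856	56.2
Maize-A.sativa_1	0.7168	58.8	0.7200	59.0	0.6992	57.3
Maize-Barley	0.7531	61.7	0.7524	61.7	0.7175	58.8
Maize-Wheat	0.6814	55.8	0.6400	52.5	0.6221	51.0
Maize-Brachy	0.8462	69.4	0.7091	58.1	0.7087	58.1
Maize-Rice	0.6886	56.4	0.7318	60.0	0.7259	59.5
Sorghum-A.sativa_2	0.7630	62.5	0.6377	52.3	0.7064	57.9
Sorghum-A.sativa_3	0.7840	64.3	0.6496	53.2	0.7208	59.1
Sorghum-A.sativa_1	0.7330	60.1	0.6432	52.7	0.7151	58.6
Sorghum-Barley	0.7703	63.1	0.6715	55.0	0.7278	59.7
Sorghum-Wheat	0.6988	57.3	0.5827	47.8	0.6434	52.7
Sorghum-Brachy	0.6946	56.9	0.6076	49.8	0.6476	53.1
Sorghum-Rice	0.5821	47.7	0.6642	54.4	0.6509	53.4
Sorghum-Maize	0.1660	13.6	0.1771	14.5	0.1610	13.2
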