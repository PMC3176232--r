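start_1	size_1	start_2	size_2	start_3	size_3
0	1	0.7885	0.161	1.0442	1
0	1	0.7965	0.1094	0.9923	1
0	1	0.5537	0.2449	0.7519	1
0	1	0.6966	0.0329	0.8482	1
0	1	0.7694	0.0983	1.0667	1
0	1	0.6776	0.2164	0.9256	1
0	1	0.7545	0.2533	0.8537	1
0	1	0.4608	0.2975	0.7556	1
0	1	0.4485	0.1563	0.6834	1
0	1	0.7247	0.2939	0.993	1
0	1	0.5944	0.2187	0.7914	1
0	1	0.5789	0.2974	0.834	1
0	1	0.6048	0.2856	0.7407	1
0	1	0.444	0.2987	0.5755	1
0	1	0.8085	0.0407	1.0827	1
0	1	0.7888	0.1638	0.9543	1
0	1	0.8289	0.1675	1.0339	1
0	1	0.5728	0.195	0.6973	1
0	1	0.6214	0.0695	0.8301	1
0	1	0.6163	0.1005	0.8584	1
0	1	0.7605	0.279	1.0583	1
0	1	0.405	0.2295	0.668	1
0	1	0.6435	0.0615	0.8186	1
0	1	0.7469	0.0498	0.8711	1
0	1	0.5985	0.1859	0.8347	1
0	1	0.5969	0.0884	0.7694	1
0	1	0.4109	0.1769	0.6416	1
0	1	0.8516	0.2639	1.043	1
0	1	0.7207	0.2318	0.9264	1
0	1	0.6655	0.106	0.9196	1
0	1	0.5372	0.0403	0.7989	1
0	1	0.7396	0.1746	1.008	1
0	1	0.6894	0.0422	0.9294	1
0	1	0.8912	0.23	1.0683	1
0	1	0.5437	0.0834	0.7206	1
0	1	0.7863	0.1637	0.9202	1
0	1	0.7325	0.2695	0.8261	1
0	1	0.4886	0.0301	0.7041	1
0	1	0.6632	0.242	0.8867	1
0	1	0.5257	0.0694	0.6339	1
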