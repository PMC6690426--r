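time	event	group
0.397	1	g1
0.113	1	g1
0.011	0	g1
0.836	1	g1
0.111	1	g1
0.351	0	g1
0.868	1	g1
0.032	0	g1
1.172	0	g1
0.384	1	g1
0.421	0	g1
0.954	0	g1
0.09	1	g1
0.894	0	g1
0.742	0	g1
1.75	0	g1
0.869	0	g1
0.88	0	g1
0.164	0	g1
0.069	0	g1
0.157	1	g2
1.404	1	g2
0.279	1	g2
0.332	1	g2
0.37	1	g2
1.444	0	g2
0.107	1	g2
0.243	1	g2
0.687	0	g2
0.683	0	g2
0.201	1	g2
0.729	0	g2
0.202	1	g2
0.099	1	g2
0.242	0	g2
0.064	1	g2
0.837	0	g2
0.066	1	g2
0.352	0	g2
0.061	1	g2
0.186	0	g3
0.267	1	g3
0.008	0	g3
0.226	1	g3
1.016	0	g3
0.094	1	g3
0.673	0	g3
1.397	0	g3
0.133	1	g3
1.004	0	g3
1.283	0	g3
0.697	1	g3
0.149	0	g3
0.397	0	g3
1.276	0	g3
1.343	0	g3
0.112	0	g3
0.328	0	g3
0.097	0	g3
1.966	0	g3
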