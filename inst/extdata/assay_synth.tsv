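substrate_mM	rate
0.09	0.413889395861414
0.125054594493582	0.578655494102496
0.173762795599492	0.728804228492111
0.241442621575175	1.07346174158221
0.335483434828345	1.29726553371583
0.466152721130809	1.53792384841058
0.647717105701037	2.01487964244258
0.9	2.43675315285268
1.25054594493582	2.81173978102644
1.73762795599492	3.04900783908594
2.41442621575175	3.68255986998279
3.35483434828345	3.77807150616988
4.66152721130809	3.81705124633892
6.47717105701036	3.66964939630394
9	4.51305342342148
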