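slaf_marker	indel	z_bsa	z_indel	p_bsa	p_indel	starred
Marker1453307	M1-1	4.931455366	2.203548955	8.16192E-07	0.02755608	FALSE
Marker442659	M2-3	-4.465945963	-0.281508006	4.71822E-06	1.221679211	FALSE
Marker647635	M3-2	4.419819573	10.63175727	7.97157E-06	0	TRUE
Marker634361	M4-1	4.442610549	11.12072674	8.88739E-06	0	TRUE
Marker1331376	M5-8	4.576942226	3.486750203	9.87833E-06	0.000488928	FALSE
Marker374140	M6-8	4.305839786	4.839172679	1.66353E-05	1.30381E-06	TRUE
Marker193648	M7-4	4.202642307	5.768207629	2.63817E-05	8.01191E-09	TRUE
Marker683605	M8-1	4.153511669	10.91958865	3.27412E-05	0	TRUE
Marker644146	M9-1	4.012944613	11.68560395	5.05806E-05	0	TRUE
Marker299828	M10-5	4.025286803	-1.337554725	5.11301E-05	1.818958368	FALSE
Marker802294	M11-4	4.050400274	1.130195268	5.69059E-05	0.258393953	FALSE
Marker339700	M12-6	4.052928074	2.937266818	5.9966E-05	0.003311191	FALSE
Marker703812	M13-1	3.993516241	11.05130924	6.51006E-05	0	TRUE
Marker628661	M14-1	3.975424118	10.77284357	7.02539E-05	0	TRUE
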