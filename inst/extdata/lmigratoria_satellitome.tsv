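sf	family	length	at	v	ab_sl	ab_nl	div_sl	div_nl	contigs	mnrpc	L1	L2	X	M3	M4	M5	M6	M7	M8	S9	S10	S11	pattern
1	LmiSat01-193	193	59.59	5	0.98225	0.6903	4.67	5.07	332	15	p	p	p	p	p	p	p	p	p	p	p	p	c
	LmiSat02-176	176	53.41	1	0.47509	0.9996	5.32	5.38	12931	100			p			p		p		p	p	p	c
	LmiSat03-195	195	58.97	6	0.29481	0.2305	5.42	5.96	1003	206	p			p									c
	LmiSat04-18	18	50	2	0.06194	0.0816	7.2	7.23	108	156										i,d		i	c
	LmiSat05-400	400	51.25	1	0.05431	0.0483	4.65	5.04	91	3										i,d		p	c
	LmiSat06-185	185	59.46	4	0.0541	0.07	4.76	5.28	274	42		p		p					p	p		p	c
	LmiSat07-5-tel	5	60	1	0.04438	0.1611	1.75	6.12	57	2868	t	t	t	t	t	t	t	t	t	t	t	t	c
	LmiSat08-168	168	57.74	1	0.03737	0.0467	4.96	4.91	327	28			p										m
	LmiSat09-181	181	60.22	5	0.02944	0.0072	5.38	7.42	45	60									p				c
	LmiSat10-9	9	55.56	2	0.02269	0.029	11.79	11.42	267	243										p		p	c
	LmiSat11-37	37	62.16	7	0.01873	0.0069	7.75	8.12	317	106				p									c
2	LmiSat12-273	273	56.41	3	0.01836	0.0113	3.5	5.29	23	16		d											c
1	LmiSat13-259	259	57.53	5	0.01697	0.0115	4.38	6.25	137	27					p								c
	LmiSat14-216	216	51.85	4	0.01426	0.0091	5.39	8.79	70	40				i,i								i	c
	LmiSat15-190	190	55.26	1	0.01426	0.0166	4.09	4.5	212	9								p					c
2	LmiSat16-278	278	62.59	1	0.0139	0.0082	2.49	3.01	17	9		d											c
	LmiSat17-75	75	57.33	1	0.01177	0.0033	5.79	6.66	112	7				p									c
	LmiSat18-210	210	60.48	1	0.01121	0.0267	6.33	4.59	6	2								p					c
	LmiSat19-89	89	60.67	1	0.01058	0.0034	3.82	6.44	10	4		p											c
	LmiSat20-15	15	53.33	1	0.01032	0.0201	12.71	14.15	190	256													nc
	LmiSat21-38	38	50	1	0.01013	0.0019	2.85	2.91	7	20										i,d			m
	LmiSat22-17	17	58.82	1	0.01	0.0092	10.81	10.28	182	426								i					c
	LmiSat23-223	223	61.43	1	0.00927	0.0106	4.42	5.73	18	10		d					d			i			c
3	LmiSat24-266	266	56.39	1	0.00895	0.0066	2.06	5.14	51	4													nc
	LmiSat25-219	219	39.73	2	0.00834	0.0105	5.88	8.2	21	5		d											c
4	LmiSat26-240	240	66.2	2	0.00809	0.00436	7.44	9.25	33	8												i	c
	LmiSat27-57	57	47.37	1	0.0079	0.0103	8.99	9.66	333	326													nc
3	LmiSat28-263	263	57.41	2	0.00768	0.0139	1.79	2.22	91	12		i,i											c
	LmiSat29-68	68	58.82	1	0.00719	0.0019	9.36	14.48	46	89				p									c
	LmiSat30-138	138	40.58	1	0.0068	0.0055	5.74	9.03	8	2									p				c
5	LmiSat31-8	8	50	3	0.00668		3.86		23	83										p	p		c
	LmiSat32-261	261	51.72	1	0.00631	0.0056	5.98	9.18	37	12		d											c
	LmiSat33-21	21	47.62	1	0.00627	0.0039	7.77	8.35	30	179										i			c
	LmiSat34-299	299	61.87	1	0.00622	0.0048	6.81	7.39	406	3		p											c
	LmiSat35-228	228	55.7	1	0.00597	0.0053	2.43	4.64	25	18													nc
	LmiSat36-15	15	60	2	0.00585	0.0093	16.88	15.12	279	302													nc
4	LmiSat37-238	238	66	1	0.00544	0.00224	6.53	6.52	111	37	i											p	c
	LmiSat38-42	42	64.29	1	0.00511	0.0046	14.56	14.94	106	692												i	c
	LmiSat39-53	53	32.08	1	0.00503	0.0013	6.79	9.17	14	119										i			c
	LmiSat40-148	148	67.57	1	0.00459	0.0023	2.35	3.05	20	4										d			c
	LmiSat41-180	180	61.67	1	0.00455	0.0058	3.38	2.14	4	6									i				c
	LmiSat42-127	127	51.18	1	0.00447	0.0012	2.02	4.6	2	2						p							c
3	LmiSat43-231	231	53.68	1	0.0044		0.68		44	3									i				m
	LmiSat44-17	17	29.41	1	0.00428	0.0005	11.45	11.3	7	53										i			c
3	LmiSat45-274	274	54.01	1	0.0042	0.0066	8.2	7.22	152	12	p,i		p	p									c
	LmiSat46-353	353	59.77	1	0.00407	0.0071	15.49	11.38	1799	2													
	LmiSat47-41	41	41.46	1	0.00369	0.0058	12.46	13.22	48	394					p								c
	LmiSat48-220	220	58.18	1	0.00366	0.0011	3.8	7.74	18	3													nc
	LmiSat49-47	47	42.55	1	0.00362	0.0113	6.24	6.7	127	282				p									c
5	LmiSat50-16	16	56.25	2	0.00331	0.0169	8.31	8.24	54	64										i			c
4	LmiSat51-241	241	63.9	1	0.00294	0.0058	7.32	3.97	33	138		i											c
	LmiSat52-143	143	51.75	1	0.00257	0.0076	22.15	14.01	1796	3													
	LmiSat53-47	47	40.43	1	0.00248	0.019	3.16	5.2	9	23										i			c
3	LmiSat54-272	272	56.25	1	0.00244	0.0051	4.55	4.15	164	51			p	i			i	p	d				m
	LmiSat55-90	90	35.56	1	0.00164	0.0074	15.62	8.57	4	3													nc
	LmiSat56-19	19	52.63	4	0.00083	0.0067	5.09	4.31	15	97							p			i			m
	LmiSat57-230	230	63.04	1	0.00052	0.0047	18.21	3.4	212	25													
	LmiSat58-86	86	41.86	1	0.00008	0.0127	5.99	3.12	10	4													nc
5	LmiSat59-16	16	43.75	3	0.00004	0.0049	18.23	14.54	13	13													nc
	LmiSat60-255	255	52.94	1	0.00004	0.0053	1.03	0.99	0	0													nc
	LmiSat61-63	63	42.86	1	0.00002	0.0062	14.99	4.6	1	11													nc
	LmiSat62-23	23	43.48	1		0.0045		4.57	1	9								p					c
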