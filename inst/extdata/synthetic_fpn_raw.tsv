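roi_id	name	x	y	z	lobe	network	atlas
r01	synAAL region 1	-60	-88	-20	frontal	FPN	synAAL
r02	synAAL region 2	-57	-88	-18	frontal	FPN	synAAL
r03	synAAL region 3	-54	-88	-16	frontal	FPN	synAAL
r04	synAAL region 4	-51	-88	-14	frontal	FPN	synAAL
r05	synAAL region 5	-48	-88	-12	frontal	FPN	synAAL
r06	synAAL region 6	-45	-88	-10	frontal	FPN	synAAL
r07	synAAL region 7	-42	-88	-8	parietal	FPN	synAAL
r08	synAAL region 8	-39	-88	-6	parietal	FPN	synAAL
r09	synAAL region 9	-36	-88	-4	parietal	FPN	synAAL
r10	synAAL region 10	-33	-88	-2	parietal	FPN	synAAL
r01	synDosenbach160 region 1	-30	-88	0	frontal	FPN	synDosenbach160
r02	synDosenbach160 region 2	-27	-88	2	frontal	FPN	synDosenbach160
r03	synDosenbach160 region 3	-24	-88	4	frontal	FPN	synDosenbach160
r04	synDosenbach160 region 4	-21	-88	6	frontal	FPN	synDosenbach160
r05	synDosenbach160 region 5	-18	-88	8	frontal	FPN	synDosenbach160
r06	synDosenbach160 region 6	-15	-88	10	frontal	FPN	synDosenbach160
r07	synDosenbach160 region 7	-12	-88	12	frontal	FPN	synDosenbach160
r08	synDosenbach160 region 8	-9	-88	14	frontal	FPN	synDosenbach160
r09	synDosenbach160 region 9	-6	-88	16	frontal	FPN	synDosenbach160
r10	synDosenbach160 region 10	-3	-88	18	frontal	FPN	synDosenbach160
r11	synDosenbach160 region 11	0	-88	20	frontal	FPN	synDosenbach160
r12	synDosenbach160 region 12	3	-88	22	frontal	FPN	synDosenbach160
r13	synDosenbach160 region 13	6	-88	24	frontal	FPN	synDosenbach160
r14	synDosenbach160 region 14	9	-88	26	parietal	FPN	synDosenbach160
r15	synDosenbach160 region 15	12	-88	28	parietal	FPN	synDosenbach160
r16	synDosenbach160 region 16	15	-88	30	parietal	FPN	synDosenbach160
r17	synDosenbach160 region 17	18	-88	32	parietal	FPN	synDosenbach160
r18	synDosenbach160 region 18	21	-88	34	parietal	FPN	synDosenbach160
r19	synDosenbach160 region 19	24	-88	36	parietal	FPN	synDosenbach160
r20	synDosenbach160 region 20	27	-88	38	parietal	FPN	synDosenbach160
r21	synDosenbach160 region 21	30	-88	40	parietal	FPN	synDosenbach160
r01	synPower264 region 1	33	-88	42	frontal	FPN	synPower264
r02	synPower264 region 2	36	-88	44	frontal	FPN	synPower264
r03	synPower264 region 3	39	-88	46	frontal	FPN	synPower264
r04	synPower264 region 4	42	-88	48	frontal	FPN	synPower264
r05	synPower264 region 5	45	-88	-20	frontal	FPN	synPower264
r06	synPower264 region 6	48	-88	-18	frontal	FPN	synPower264
r07	synPower264 region 7	51	-88	-16	frontal	FPN	synPower264
r08	synPower264 region 8	54	-88	-14	frontal	FPN	synPower264
r09	synPower264 region 9	57	-88	-12	frontal	FPN	synPower264
r10	synPower264 region 10	60	-88	-10	frontal	FPN	synPower264
r11	synPower264 region 11	-60	-77	-8	frontal	FPN	synPower264
r12	synPower264 region 12	-57	-77	-6	frontal	FPN	synPower264
r13	synPower264 region 13	-54	-77	-4	frontal	FPN	synPower264
r14	synPower264 region 14	-51	-77	-2	frontal	FPN	synPower264
r15	synPower264 region 15	-48	-77	0	frontal	FPN	synPower264
r16	synPower264 region 16	-45	-77	2	frontal	FPN	synPower264
r17	synPower264 region 17	-42	-77	4	frontal	FPN	synPower264
r18	synPower264 region 18	-39	-77	6	parietal	FPN	synPower264
r19	synPower264 region 19	-36	-77	8	parietal	FPN	synPower264
r20	synPower264 region 20	-33	-77	10	parietal	FPN	synPower264
r21	synPower264 region 21	-30	-77	12	parietal	FPN	synPower264
r22	synPower264 region 22	-27	-77	14	parietal	FPN	synPower264
r23	synPower264 region 23	-24	-77	16	parietal	FPN	synPower264
r24	synPower264 region 24	-21	-77	18	parietal	FPN	synPower264
r25	synPower264 region 25	-18	-77	20	temporal	FPN	synPower264
r01	synWillard499 region 1	-15	-77	22	frontal	ECN	synWillard499
r02	synWillard499 region 2	-12	-77	24	frontal	ECN	synWillard499
r03	synWillard499 region 3	-9	-77	26	frontal	ECN	synWillard499
r04	synWillard499 region 4	-6	-77	28	frontal	ECN	synWillard499
r05	synWillard499 region 5	-3	-77	30	frontal	ECN	synWillard499
r06	synWillard499 region 6	0	-77	32	frontal	ECN	synWillard499
r07	synWillard499 region 7	3	-77	34	frontal	ECN	synWillard499
r08	synWillard499 region 8	6	-77	36	frontal	ECN	synWillard499
r09	synWillard499 region 9	9	-77	38	frontal	ECN	synWillard499
r10	synWillard499 region 10	12	-77	40	frontal	ECN	synWillard499
r11	synWillard499 region 11	15	-77	42	frontal	ECN	synWillard499
r12	synWillard499 region 12	18	-77	44	parietal	ECN	synWillard499
r13	synWillard499 region 13	21	-77	46	parietal	ECN	synWillard499
r14	synWillard499 region 14	24	-77	48	parietal	ECN	synWillard499
r15	synWillard499 region 15	27	-77	-20	parietal	ECN	synWillard499
r16	synWillard499 region 16	30	-77	-18	parietal	ECN	synWillard499
r17	synWillard499 region 17	33	-77	-16	parietal	ECN	synWillard499
r18	synWillard499 region 18	36	-77	-14	temporal	ECN	synWillard499
r19	synWillard499 region 19	39	-77	-12	limbic	ECN	synWillard499
r20	synWillard499 region 20	42	-77	-10	cerebellum	ECN	synWillard499
r21	synWillard499 region 21	45	-77	-8	cerebellum	ECN	synWillard499
r22	synWillard499 region 22	48	-77	-6	cerebellum	ECN	synWillard499
r23	synWillard499 region 23	51	-77	-4	cerebellum	ECN	synWillard499
r24	synWillard499 region 24	54	-77	-2	cerebellum	ECN	synWillard499
r01	synGao32 region 1	57	-77	0	frontal	FPN	synGao32
r02	synGao32 region 2	60	-77	2	frontal	FPN	synGao32
r03	synGao32 region 3	-60	-66	4	frontal	FPN	synGao32
r04	synGao32 region 4	-57	-66	6	frontal	FPN	synGao32
r05	synGao32 region 5	-54	-66	8	parietal	FPN	synGao32
r06	synGao32 region 6	-51	-66	10	parietal	FPN	synGao32
r07	synGao32 region 7	-48	-66	12	parietal	FPN	synGao32
r08	synGao32 region 8	-45	-66	14	insula	FPN	synGao32
r09	synGao32 region 9	-42	-66	16	insula	FPN	synGao32
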