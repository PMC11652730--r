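id	contig	start_mb	end_mb	size_mb	age_myr	ors
Inv2	IpsContig2	12.67	16.71	4.04	0.5
Inv3	IpsContig3	1.11	1.25	0.14	1.1
Inv5	IpsContig5	0.00	10.84	10.84	1.3	ItypOR33;ItypOR41;ItypOR40;ItypOR10;ItypOR47;ItypOR50;ItypOR29;ItypOR43JOI;ItypOR34;ItypOR52NTE;ItypOR4;ItypOR3;ItypOR53;ItypOR2;ItypOR19
Inv6	IpsContig6	8.93	9.27	0.34	1.0
Inv7.1	IpsContig7	0.00	0.67	0.67	1.7
Inv7.2	IpsContig7	0.00	6.92	6.92	1.1	ItypOR1;ItypOR17
Inv9	IpsContig9	1.71	5.01	3.30	0.6
Inv10	IpsContig10	6.05	6.13	0.08	1.8
Inv12	IpsContig12	3.63	3.70	0.07	1.5
Inv13	IpsContig13	0.00	4.50	4.50	1.7	ItypOR28;ItypOR23;ItypOR49;ItypOR27
Inv14.1	IpsContig14	0.00	2.08	2.08	1.9	ItypOR36;ItypOR44;ItypOR18JF;ItypOR20NTE
Inv14.2	IpsContig14	2.08	2.75	0.67	1.0
Inv14.3	IpsContig14	2.78	3.54	0.76	2.1
Inv14.4	IpsContig14	3.73	3.84	0.11	2.1
Inv14.5	IpsContig14	4.23	4.80	0.57	2.3
Inv14.6	IpsContig14	0.00	2.48	2.48	0.6	ItypOR36;ItypOR44;ItypOR18JF;ItypOR20NTE
Inv15	IpsContig15	0.86	2.78	1.92	1.9
Inv16.1	IpsContig16	0.00	4.83	4.83	1.6	ItypOR58;ItypOR9;ItypOR11;ItypOR31;ItypOR30;ItypOR16;ItypOR35JF
Inv16.2	IpsContig16	0.00	4.83	4.83	0.7	ItypOR58;ItypOR9;ItypOR11;ItypOR31;ItypOR30;ItypOR16;ItypOR35JF
Inv17	IpsContig17	2.48	2.69	0.21	2.2
Inv18	IpsContig18	0.00	2.32	2.32	2.1
Inv22.1	IpsContig22	0.00	0.32	0.32	2.1
Inv22.2	IpsContig22	0.42	0.65	0.23	2.1
Inv22.3	IpsContig22	0.68	1.91	1.23	2.0	ItypOR22CTE
Inv22.4	IpsContig22	1.92	2.12	0.20	2.1
Inv22.5	IpsContig22	0.00	2.24	2.24	0.6	ItypOR22CTE
Inv23.1	IpsContig23	0.00	2.10	2.10	1.4	ItypOR58;ItypOR9
Inv23.2	IpsContig23	0.26	2.10	1.84	0.6	ItypOR58;ItypOR9
Inv26	IpsContig26	0.12	0.22	0.10	2.6
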