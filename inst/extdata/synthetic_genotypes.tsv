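individual	chrom	pos	genotype	qual	cov	lib_reads
ind0001	chrA	61217	P1	155.332	2.36905	168704
ind0001	chrA	152144	P1	234.837	2.16327	168704
ind0001	chrA	250952	P1	187.258	7.18358	168704
ind0001	chrA	357223	P1	230.502	7.00475	168704
ind0001	chrA	445024	P1	237.062	2.39817	168704
ind0001	chrA	543737	P1	159.674	3.81918	168704
ind0001	chrA	642212	P1	152.422	4.57529	168704
ind0001	chrA	730587	P1	153.652	6.52803	168704
ind0001	chrA	834978	P1	248.744	4.65112	168704
ind0001	chrA	946316	P1	170.781	7.08491	168704
ind0001	chrA	1064146	P1	190.749	5.09704	168704
ind0001	chrA	1159673	P1	211.756	4.72458	168704
ind0001	chrA	1238942	P1	196.149	7.22071	168704
ind0001	chrA	1368822	P1	195.513	3.42236	168704
ind0001	chrA	1458705	P1	198.557	1.9303	168704
ind0001	chrA	1562985	P1	216.65	7.3744	168704
ind0001	chrA	1646170	H	196.665	2.2879	168704
ind0001	chrA	1746446	P2	160.392	5.54218	168704
ind0001	chrA	1867965	H	203.217	1.11154	168704
ind0001	chrA	1951109	H	186.693	7.11447	168704
ind0001	chrB	46702	P1	155.479	4.90058	168704
ind0001	chrB	161162	H	241.988	4.81618	168704
ind0001	chrB	237578	H	225.68	0.862083	168704
ind0001	chrB	348158	H	150.257	2.33214	168704
ind0001	chrB	441341	H	160.699	8.04218	168704
ind0001	chrB	530933	H	235.338	4.14141	168704
ind0001	chrB	649803	P2	180.328	2.86487	168704
ind0001	chrB	732222	P2	231.107	7.28958	168704
ind0001	chrB	833033	P2	234.502	1.47779	168704
ind0001	chrB	953072	P2	196.747	7.13738	168704
ind0001	chrB	1036495	H	202.702	1.50569	168704
ind0001	chrB	1158687	H	195.363	4.72683	168704
ind0001	chrB	1252600	H	177.866	9.47329	168704
ind0001	chrB	1363262	H	179.61	4.37827	168704
ind0001	chrB	1465847	H	169.648	1.01043	168704
ind0002	chrA	61217	H	188.156	6.09213	196262
ind0002	chrA	152144	H	172.08	1.19763	196262
ind0002	chrA	250952	H	201.986	6.67203	196262
ind0002	chrA	357223	H	169.3	4.658	196262
ind0002	chrA	445024	H	190.674	1.24482	196262
ind0002	chrA	543737	H	249.219	5.14711	196262
ind0002	chrA	642212	H	195.218	7.48061	196262
ind0002	chrA	730587	H	245.97	5.07799	196262
ind0002	chrA	834978	H	230.957	6.70361	196262
ind0002	chrA	946316	P1	204.089	1.41926	196262
ind0002	chrA	1064146	H	238.043	4.53485	196262
ind0002	chrA	1159673	H	173.821	6.0358	196262
ind0002	chrA	1238942	H	194.706	1.28582	196262
ind0002	chrA	1368822	H	155.845	4.10701	196262
ind0002	chrA	1458705	H	171.961	4.2427	196262
ind0002	chrA	1562985	H	224.122	5.30476	196262
ind0002	chrA	1646170	H	173.283	6.61798	196262
ind0002	chrA	1746446	H	194.583	4.48368	196262
ind0002	chrA	1867965	H	169.201	6.97119	196262
ind0002	chrA	1951109	H	235.225	4.57592	196262
ind0002	chrB	46702	H	199.516	4.74675	196262
ind0002	chrB	161162	H	248.096	1.15819	196262
ind0002	chrB	237578	H	226.837	6.18039	196262
ind0002	chrB	348158	H	227.189	5.87116	196262
ind0002	chrB	441341	H	249.326	5.50098	196262
ind0002	chrB	530933	H	156.003	4.81889	196262
ind0002	chrB	649803	H	154.27	4.63833	196262
ind0002	chrB	732222	P1	152.836	6.07676	196262
ind0002	chrB	833033	P1	155.216	6.76939	196262
ind0002	chrB	953072	H	225.948	4.20993	196262
ind0002	chrB	1036495	H	153.291	3.27186	196262
ind0002	chrB	1158687	H	225.091	3.17652	196262
ind0002	chrB	1252600	H	214.91	7.17904	196262
ind0002	chrB	1363262	H	159.471	2.55082	196262
ind0002	chrB	1465847	H	249.755	4.87625	196262
ind0003	chrA	61217	H	188.04	3.6618	186013
ind0003	chrA	152144	H	225.1	3.62621	186013
ind0003	chrA	250952	H	235.592	4.24491	186013
ind0003	chrA	357223	P2	159.713	4.91	186013
ind0003	chrA	445024	H	213.976	2.31174	186013
ind0003	chrA	543737	H	151.494	6.10884	186013
ind0003	chrA	642212	H	235.555	4.46809	186013
ind0003	chrA	730587	H	163.834	1.48312	186013
ind0003	chrA	834978	H	238.727	4.50138	186013
ind0003	chrA	946316	H	220.509	9.0167	186013
ind0003	chrA	1064146	H	201.861	3.74564	186013
ind0003	chrA	1159673	H	202.008	4.79214	186013
ind0003	chrA	1238942	H	192.908	1.88422	186013
ind0003	chrA	1368822	H	203.664	3.06311	186013
ind0003	chrA	1458705	H	226.189	10.4828	186013
ind0003	chrA	1562985	H	248.07	3.7232	186013
ind0003	chrA	1646170	P2	167.915	3.81883	186013
ind0003	chrA	1746446	H	176.709	7.62171	186013
ind0003	chrA	1867965	H	179.783	9.3573	186013
ind0003	chrA	1951109	H	179.787	2.68061	186013
ind0003	chrB	46702	P1	198.907	5.636	186013
ind0003	chrB	161162	P1	178.57	7.96057	186013
ind0003	chrB	237578	P1	202.018	2.22142	186013
ind0003	chrB	348158	P1	230.721	2.17765	186013
ind0003	chrB	441341	P1	175.535	6.44391	186013
ind0003	chrB	530933	P1	214.601	2.53335	186013
ind0003	chrB	649803	P1	180.497	5.62837	186013
ind0003	chrB	732222	P1	156.094	3.88923	186013
ind0003	chrB	833033	P1	191.726	13.0229	186013
ind0003	chrB	953072	P1	247.017	2.75463	186013
ind0003	chrB	1036495	P1	173.715	4.06114	186013
ind0003	chrB	1158687	P1	159.09	4.97379	186013
ind0003	chrB	1252600	P1	221.804	3.05394	186013
ind0003	chrB	1363262	P1	199.694	5.4233	186013
ind0003	chrB	1465847	P1	210.946	8.94702	186013
ind0004	chrA	61217	H	170.286	3.11028	192877
ind0004	chrA	152144	H	213.832	3.20715	192877
ind0004	chrA	250952	H	158.122	8.25708	192877
ind0004	chrA	357223	H	231.957	6.45946	192877
ind0004	chrA	445024	H	212.277	2.77005	192877
ind0004	chrA	543737	H	169.133	14.4217	192877
ind0004	chrA	642212	H	199.215	2.3013	192877
ind0004	chrA	730587	H	247.525	4.36417	192877
ind0004	chrA	834978	H	188.152	6.75895	192877
ind0004	chrA	946316	H	154.507	4.07781	192877
ind0004	chrA	1064146	H	172.702	3.3195	192877
ind0004	chrA	1159673	H	206.703	6.43533	192877
ind0004	chrA	1238942	H	234.673	3.23408	192877
ind0004	chrA	1368822	P1	185.513	10.3914	192877
ind0004	chrA	1458705	P1	169.508	5.97368	192877
ind0004	chrA	1562985	P1	241.013	5.96458	192877
ind0004	chrA	1646170	P1	168.157	5.23847	192877
ind0004	chrA	1746446	P1	170.642	1.6924	192877
ind0004	chrA	1867965	P1	187.863	5.67378	192877
ind0004	chrA	1951109	P1	184.135	5.61802	192877
ind0004	chrB	46702	H	245.92	9.17156	192877
ind0004	chrB	161162	H	170.318	7.23993	192877
ind0004	chrB	237578	H	212.624	5.75501	192877
ind0004	chrB	348158	H	205.309	12.013	192877
ind0004	chrB	441341	H	240.354	5.50114	192877
ind0004	chrB	530933	H	201.924	3.2521	192877
ind0004	chrB	649803	H	230.54	4.71771	192877
ind0004	chrB	732222	P2	208.426	2.31135	192877
ind0004	chrB	833033	P2	164.257	2.48329	192877
ind0004	chrB	953072	P2	231.738	6.94119	192877
ind0004	chrB	1036495	P2	190.607	2.62502	192877
ind0004	chrB	1158687	P2	187.247	5.19111	192877
ind0004	chrB	1252600	P2	153.549	7.70855	192877
ind0004	chrB	1363262	P2	209.485	3.9911	192877
ind0004	chrB	1465847	P2	164.865	7.79691	192877
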