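gene	chromosome	start
g1_001	1	1
g1_002	1	1000001
g1_003	1	2000001
g1_004	1	3000001
g1_005	1	4000001
g1_006	1	5000001
g1_007	1	6000001
g1_008	1	7000001
g1_009	1	8000001
g1_010	1	9000001
g1_011	1	10000001
g1_012	1	11000001
g1_013	1	12000001
g1_014	1	13000001
g1_015	1	14000001
g1_016	1	15000001
g1_017	1	16000001
g1_018	1	17000001
g1_019	1	18000001
g1_020	1	19000001
g1_021	1	20000001
g1_022	1	21000001
g1_023	1	22000001
g1_024	1	23000001
g1_025	1	24000001
g1_026	1	25000001
g1_027	1	26000001
g1_028	1	27000001
g1_029	1	28000001
g1_030	1	29000001
g1_031	1	30000001
g1_032	1	31000001
g1_033	1	32000001
g1_034	1	33000001
g1_035	1	34000001
g1_036	1	35000001
g1_037	1	36000001
g1_038	1	37000001
g1_039	1	38000001
g1_040	1	39000001
g1_041	1	40000001
g1_042	1	41000001
g1_043	1	42000001
g1_044	1	43000001
g1_045	1	44000001
g1_046	1	45000001
g1_047	1	46000001
g1_048	1	47000001
g1_049	1	48000001
g1_050	1	49000001
g2_001	2	1
g2_002	2	1000001
g2_003	2	2000001
g2_004	2	3000001
g2_005	2	4000001
g2_006	2	5000001
g2_007	2	6000001
g2_008	2	7000001
g2_009	2	8000001
g2_010	2	9000001
g2_011	2	10000001
g2_012	2	11000001
g2_013	2	12000001
g2_014	2	13000001
g2_015	2	14000001
g2_016	2	15000001
g2_017	2	16000001
g2_018	2	17000001
g2_019	2	18000001
g2_020	2	19000001
g2_021	2	20000001
g2_022	2	21000001
g2_023	2	22000001
g2_024	2	23000001
g2_025	2	24000001
g2_026	2	25000001
g2_027	2	26000001
g2_028	2	27000001
g2_029	2	28000001
g2_030	2	29000001
g2_031	2	30000001
g2_032	2	31000001
g2_033	2	32000001
g2_034	2	33000001
g2_035	2	34000001
g2_036	2	35000001
g2_037	2	36000001
g2_038	2	37000001
g2_039	2	38000001
g2_040	2	39000001
g2_041	2	40000001
g2_042	2	41000001
g2_043	2	42000001
g2_044	2	43000001
g2_045	2	44000001
g2_046	2	45000001
g2_047	2	46000001
g2_048	2	47000001
g2_049	2	48000001
g2_050	2	49000001
g3_001	3	1
g3_002	3	1000001
g3_003	3	2000001
g3_004	3	3000001
g3_005	3	4000001
g3_006	3	5000001
g3_007	3	6000001
g3_008	3	7000001
g3_009	3	8000001
g3_010	3	9000001
g3_011	3	10000001
g3_012	3	11000001
g3_013	3	12000001
g3_014	3	13000001
g3_015	3	14000001
g3_016	3	15000001
g3_017	3	16000001
g3_018	3	17000001
g3_019	3	18000001
g3_020	3	19000001
g3_021	3	20000001
g3_022	3	21000001
g3_023	3	22000001
g3_024	3	23000001
g3_025	3	24000001
g3_026	3	25000001
g3_027	3	26000001
g3_028	3	27000001
g3_029	3	28000001
g3_030	3	29000001
g3_031	3	30000001
g3_032	3	31000001
g3_033	3	32000001
g3_034	3	33000001
g3_035	3	34000001
g3_036	3	35000001
g3_037	3	36000001
g3_038	3	37000001
g3_039	3	38000001
g3_040	3	39000001
g3_041	3	40000001
g3_042	3	41000001
g3_043	3	42000001
g3_044	3	43000001
g3_045	3	44000001
g3_046	3	45000001
g3_047	3	46000001
g3_048	3	47000001
g3_049	3	48000001
g3_050	3	49000001
g4_001	4	1
g4_002	4	1000001
g4_003	4	2000001
g4_004	4	3000001
g4_005	4	4000001
g4_006	4	5000001
g4_007	4	6000001
g4_008	4	7000001
g4_009	4	8000001
g4_010	4	9000001
g4_011	4	10000001
g4_012	4	11000001
g4_013	4	12000001
g4_014	4	13000001
g4_015	4	14000001
g4_016	4	15000001
g4_017	4	16000001
g4_018	4	17000001
g4_019	4	18000001
g4_020	4	19000001
g4_021	4	20000001
g4_022	4	21000001
g4_023	4	22000001
g4_024	4	23000001
g4_025	4	24000001
g4_026	4	25000001
g4_027	4	26000001
g4_028	4	27000001
g4_029	4	28000001
g4_030	4	29000001
g4_031	4	30000001
g4_032	4	31000001
g4_033	4	32000001
g4_034	4	33000001
g4_035	4	34000001
g4_036	4	35000001
g4_037	4	36000001
g4_038	4	37000001
g4_039	4	38000001
g4_040	4	39000001
g4_041	4	40000001
g4_042	4	41000001
g4_043	4	42000001
g4_044	4	43000001
g4_045	4	44000001
g4_046	4	45000001
g4_047	4	46000001
g4_048	4	47000001
g4_049	4	48000001
g4_050	4	49000001
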