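sample_id	substrate	t_days	mu_B	T_d	mu_S_C	mu_S_N	f0_pct
U1365 8H-2	Acetate	21	0.284	2.4	0.032	0.052	N.A.
U1365 8H-2	AAmix	21	0.086	8.0	0.022	0.047	96.6
U1365 8H-2	Bicarbonate	21	0.152	4.6	0.000	0.060	82.1
U1365 8H-2	Glucose	21	0.358	1.9	0.010	0.047	N.A.
U1365 8H-2	Ammonia	21	0.111	6.3	nm	0.042	47.4
U1365 8H-2	Pyruvate	21	0.341	2.0	0.025	0.063	N.A.
U1365 9H-3	Acetate	21	0.039	17.9	0.002	0.003	99.1
U1365 9H-3	AAmix	21	0.136	5.1	0.023	0.073	98.9
U1365 9H-3	Bicarbonate	21	0.046	15.1	0.000	0.027	38.0
U1365 9H-3	Glucose	21	0.092	7.5	0.006	0.043	89.0
U1365 9H-3	Ammonia	21	0.084	8.2	nm	0.059	92.4
U1365 9H-3	Pyruvate	21	0.131	5.3	0.010	0.037	87.2
U1368 1H-2	Acetate	21	0.175	4.0	0.004	0.006	N.A.
U1368 1H-2	AAmix	21	0.166	4.2	0.021	0.032	88.7
U1368 1H-2	Bicarbonate	21	0.211	3.3	0.001	0.014	93.9
U1368 1H-2	Glucose	21	0.176	3.9	0.001	0.037	67.1
U1368 1H-2	Ammonia	21	0.157	4.4	nm	0.020	86.8
U1368 1H-2	Pyruvate	21	0.315	2.2	0.023	0.053	74.0
U1368 2H-5	Acetate	21	0.441	1.6	0.027	0.050	N.A.
U1368 2H-5	AAmix	21	0.286	2.4	0.013	0.022	24.1
U1368 2H-5	Bicarbonate	21	0.344	2.0	0.000	0.068	N.A.
U1368 2H-5	Glucose	21	0.487	1.4	0.022	0.042	N.A.
U1368 2H-5	Ammonia	21	0.278	2.5	nm	0.024	N.A.
U1368 2H-5	Pyruvate	21	0.445	1.6	0.014	0.031	N.A.
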