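marker_id	chrom
mk_A_0001	1A
mk_A_0002	2A
mk_A_0003	3A
mk_A_0004	4A
mk_A_0005	5A
mk_A_0006	6A
mk_A_0007	7A
mk_A_0008	1A
mk_A_0009	2A
mk_A_0010	3A
mk_A_0011	4A
mk_A_0012	5A
mk_A_0013	6A
mk_A_0014	7A
mk_A_0015	1A
mk_A_0016	2A
mk_A_0017	3A
mk_A_0018	4A
mk_A_0019	5A
mk_A_0020	6A
mk_A_0021	7A
mk_A_0022	1A
mk_A_0023	2A
mk_A_0024	3A
mk_A_0025	4A
mk_A_0026	5A
mk_A_0027	6A
mk_A_0028	7A
mk_A_0029	1A
mk_A_0030	2A
mk_B_0001	1B
mk_B_0002	2B
mk_B_0003	3B
mk_B_0004	4B
mk_B_0005	5B
mk_B_0006	6B
mk_B_0007	7B
mk_B_0008	1B
mk_B_0009	2B
mk_B_0010	3B
mk_B_0011	4B
mk_B_0012	5B
mk_B_0013	6B
mk_B_0014	7B
mk_B_0015	1B
mk_B_0016	2B
mk_B_0017	3B
mk_B_0018	4B
mk_B_0019	5B
mk_B_0020	6B
mk_B_0021	7B
mk_B_0022	1B
mk_B_0023	2B
mk_B_0024	3B
mk_B_0025	4B
mk_B_0026	5B
mk_D_0001	1D
mk_D_0002	2D
mk_D_0003	3D
mk_D_0004	4D
mk_D_0005	5D
mk_D_0006	6D
mk_D_0007	7D
mk_D_0008	1D
mk_D_0009	2D
mk_D_0010	3D
mk_D_0011	4D
mk_D_0012	5D
mk_D_0013	6D
mk_D_0014	7D
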