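snp_id	chrom	pos	block_id	hap1_count	hap2_count	assay
toy001	chr1	1000	1	4	5	RNA_rep1
toy002	chr1	1500	1	4	5	RNA_rep1
toy003	chr1	2000	1	4	5	RNA_rep1
toy004	chr1	2500	1	4	5	RNA_rep1
toy005	chr1	3000	1	4	5	RNA_rep1
toy006	chr1	3500	1	3	2	RNA_rep1
toy007	chr1	4000	1	3	2	RNA_rep1
toy008	chr1	4500	1	3	2	RNA_rep1
toy009	chr1	5000	1	3	2	RNA_rep1
toy010	chr1	5500	1	3	2	RNA_rep1
toy011	chr1	6000	1	20	15	RNA_rep1
toy012	chr1	6500	1	20	15	RNA_rep1
toy013	chr1	7000	1	20	15	RNA_rep1
toy014	chr1	7500	1	20	15	RNA_rep1
toy015	chr1	8000	1	20	15	RNA_rep1
toy016	chr1	8500	1	20	15	RNA_rep1
toy017	chr1	9000	1	20	15	RNA_rep1
toy018	chr1	9500	1	20	15	RNA_rep1
toy019	chr1	10000	1	20	15	RNA_rep1
toy020	chr1	10500	1	20	15	RNA_rep1
toy021	chr1	11000	1	20	15	RNA_rep1
toy022	chr1	11500	1	20	15	RNA_rep1
toy023	chr1	12000	1	20	15	RNA_rep1
toy024	chr1	12500	1	20	15	RNA_rep1
toy025	chr1	13000	1	20	15	RNA_rep1
toy026	chr1	13500	1	20	15	RNA_rep1
toy027	chr1	14000	1	20	15	RNA_rep1
toy028	chr1	14500	1	20	15	RNA_rep1
toy029	chr1	15000	1	20	15	RNA_rep1
toy030	chr1	15500	1	20	15	RNA_rep1
toy031	chr1	16000	1	20	15	RNA_rep1
toy032	chr1	16500	1	20	15	RNA_rep1
toy033	chr1	17000	1	20	15	RNA_rep1
toy034	chr1	17500	1	20	15	RNA_rep1
toy035	chr1	18000	1	20	15	RNA_rep1
toy036	chr1	18500	1	20	15	RNA_rep1
toy037	chr1	19000	1	20	15	RNA_rep1
toy038	chr1	19500	1	20	15	RNA_rep1
toy039	chr1	20000	1	20	15	RNA_rep1
toy040	chr1	20500	1	20	15	RNA_rep1
toy041	chr1	21000	1	20	15	RNA_rep1
toy042	chr1	21500	1	20	15	RNA_rep1
toy043	chr1	22000	1	20	15	RNA_rep1
toy044	chr1	22500	1	20	15	RNA_rep1
toy045	chr1	23000	1	20	15	RNA_rep1
toy046	chr1	23500	1	20	15	RNA_rep1
toy047	chr1	24000	1	20	15	RNA_rep1
toy048	chr1	24500	1	20	15	RNA_rep1
toy049	chr1	25000	1	20	15	RNA_rep1
toy050	chr1	25500	1	20	15	RNA_rep1
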