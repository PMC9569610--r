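patient_id	disease	total_uniquely_mapped_reads	five_gene	three_gene	spanning_pairs	spanning_unique_reads	read_evidence_level	five_point	five_border	three_point	three_border
P17	ARMS	17891296	COPS3	TOM1L2	11	9	1.12	17:17276035:-	end of exon	17:17898674:-	start of exon
P17	ARMS	17891296	HTT	ADD1	7	5	0.67	4:3174799:+	end of exon	4:2904764:+	start of exon
P17	ARMS	17891296	NCOA1	DTNB	6	9	0.84	2:24728476:+	end of exon	2:25531597:-	start of exon
P19	ARMS	20614167	AC138409.2	NAIP	3	4	0.34	5:34175822:-	end of exon	5:71003857:-	start of exon
P19	ARMS	20614167	NLRP2	RPL36A	3	4	0.34	19:54973997:+	in exon	X:101395351:+	in exon
P19	ARMS	20614167	RPL36A	NLRP2	3	5	0.39	X:101391808:+	in exon	19:54973973:+	in intron
P19	ARMS	20614167	WWTR1	LINC01986	6	5	0.53	3:149572864:-	end of exon	3:23968:+	start of exon
P20	ARMS	18472958	AP1B1	CHEK2	3	2	0.27	22:29349218:-	end of exon	22:28710059:-	start of exon
P20	ARMS	18472958	IGK@	BAGE2	54	17	3.84	2:89631593:-	end of exon	21:10499475:+	start of exon
P20	ARMS	18472958	PITPNC1	CACNG4	3	2	0.27	17:67532950:+	end of exon	17:67018189:+	start of exon
P20	ARMS	18472958	PLAA	MOB3B	8	3	0.60	9:26910338:-	end of exon	9:27330616:-	start of exon
P20	ARMS	18472958	PTPRG	PPP4R2	3	3	0.32	3:61562372:+	end of exon	3:72998077:+	start of exon
P20	ARMS	18472958	WDR74	ACTB	3	3	0.32	11:62837505:-	in intron	7:5527639:-	in exon
P22	ARMS	17675699	GON4L	SMG5	2	5	0.40	1:155804949:-	end of exon	1:156253508:-	start of exon
P23	ARMS	18512177	BRD4	LEUTX	3	11	0.76	19:15254152:-	end of exon	19:39784527:+	start of exon
P24	ARMS	19914559	ATN1	MAML2	3	9	0.60	12:6936716:+	in exon	11:96092266:-	in exon
P30	URCS	23211375	NCOA3	TBP	3	3	0.26	20:47651098:+	in exon	6:170561926:+	in exon
P30	URCS	23211375	TBP	NCOA3	3	8	0.47	6:170561939:+	in exon	20:47651071:+	in exon
P32	URCS	20217802	MEST	RGS22	2	2	0.20	7:130500532:+	end of exon	8:100093509:-	start of exon
P33	URCS	25928668	AC009021.1	RRN3	2	2	0.15	16:22613454:-	end of exon	16:15080096:-	start of exon
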