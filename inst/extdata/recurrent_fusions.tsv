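five_gene	three_gene	disease	patient_id	total_uniquely_mapped_reads	spanning_pairs	spanning_unique_reads	read_evidence_level	five_point	five_border	three_point	three_border
AC245595.1	IGK@	ARMS	P19	27247781	10	2	0.44	1:144250225:-	end of exon	2:89581140:-	start of exon
AC245595.1	IGK@	ARMS	P25	25800361	59	2	2.36	1:144250225:-	end of exon	2:89581140:-	start of exon
ELMO1	AOAH	ARMS	P18	23669117	2	3	0.21	7:36861659:-	end of exon	7:36674009:-	start of exon
ELMO1	AOAH	ARMS	P25	25800361	3	6	0.35	7:36861659:-	end of exon	7:36674009:-	start of exon
COPS4	TBC1D9	URCS	P27	28739150	4	3	0.24	4:83035298:+	end of exon	4:140679843:-	start of exon
COPS4	TBC1D9	URCS	P28	24863986	4	4	0.32	4:83035298:+	end of exon	4:140679843:-	start of exon
PICALM	SYTL2	URCS	P27	28739150	3	2	0.17	11:85974708:-	end of exon	11:85758114:-	start of exon
PICALM	SYTL2	URCS	P28	24863986	2	3	0.20	11:85974708:-	end of exon	11:85758114:-	start of exon
SMG6	VPS53	URCS	P27	28739150	121	23	5.01	17:2172658:-	end of exon	17:710613:-	start of exon
SMG6	VPS53	URCS	P28	24863986	44	21	2.61	17:2172658:-	end of exon	17:710613:-	start of exon
UBE2F	ALS2	URCS	P27	28739150	6	13	0.66	2:237973225:+	end of exon	2:201718210:-	start of exon
UBE2F	ALS2	URCS	P28	24863986	5	8	0.52	2:237973225:+	end of exon	2:201718210:-	start of exon
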