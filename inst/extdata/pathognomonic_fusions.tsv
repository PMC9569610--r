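patient_id	cohort	disease	total_uniquely_mapped_reads	five_gene	three_gene	spanning_pairs	spanning_unique_reads	read_evidence_level	five_point	five_border	three_point	three_border
P11	I	myxoid/round cell liposarcoma	2521243	FUS	DDIT3	4	6	3.97	16:31184396:+	end of exon	12:57517753:-	start of exon
P12	I	Ewing sarcoma	2837511	EWSR1	FLI1	8	4	4.23	22:29288786:+	end of exon	11:128807180:+	start of exon
P12	I	Ewing sarcoma	2837511	EWSR1	FLI1	8	2	3.52	22:29291599:+	end of exon	11:128807180:+	start of exon
P13	I	ARMS	2144348	PAX3	FOXO1	12	13	11.66	2:222220140:-	end of exon	13:40560860:-	start of exon
P14	I	ARMS	3344823	PAX3	FOXO1	3	18	6.28	2:222220140:-	end of exon	13:40560860:-	start of exon
P15	I	synovial sarcoma	2998047	SS18	SSX1	66	26	30.69	18:26032399:-	end of exon	X:48263782:+	start of exon
P16	I	synovial sarcoma	2480668	SS18	SSX2	11	20	12.50	18:26032399:-	end of exon	X:52700578:-	start of exon
P16	I	synovial sarcoma	2480668	SS18	SSX2B	11	20	12.50	18:26032399:-	end of exon	X:52757854:+	start of exon
P18	II	ARMS	17582558	PAX3	FOXO1	11	16	1.54	2:222220140:-	end of exon	13:40560860:-	start of exon
P25	II	ARMS	18832810	PAX3	FOXO1	13	13	1.38	2:222220140:-	end of exon	13:40560860:-	start of exon
P26	II	Ewing sarcoma	22414225	EWSR1	ERG	3	5	0.36	22:29287134:+	end of exon	21:38392444:-	start of exon
P27	II	URCS	21846511	EWSR1	NFATC2	19	12	1.42	22:29282557:+	end of exon	20:51516955:-	start of exon
P28	II	URCS	18512302	EWSR1	NFATC2	19	13	1.73	22:29282557:+	end of exon	20:51516955:-	start of exon
P29	II	Ewing sarcoma	21344451	EWSR1	FLI1	4	5	0.42	22:29287134:+	end of exon	11:128805366:+	start of exon
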