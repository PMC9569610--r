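disease	five_gene	three_gene
ARMS	PAX3	FOXO1
ARMS	PAX7	FOXO1
Ewing sarcoma	EWSR1	FLI1
Ewing sarcoma	EWSR1	ERG
URCS	EWSR1	FLI1
URCS	EWSR1	ERG
URCS	EWSR1	NFATC2
myxoid/round cell liposarcoma	FUS	DDIT3
synovial sarcoma	SS18	SSX1
synovial sarcoma	SS18	SSX2
synovial sarcoma	SS18	SSX2B
synovial sarcoma	SS18	SSX4
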