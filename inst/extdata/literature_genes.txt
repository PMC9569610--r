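PAX3
PAX7
FOXO1
EWSR1
FLI1
ERG
NFATC2
FUS
DDIT3
SS18
SSX1
SSX2
SSX2B
SSX4
COPS3
TOM1L2
HTT
NCOA1
NAIP
RPL36A
WWTR1
AP1B1
CHEK2
IGK@
PITPNC1
PLAA
PTPRG
ACTB
GON4L
BRD4
MAML2
NCOA3
TBP
MEST
RRN3
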