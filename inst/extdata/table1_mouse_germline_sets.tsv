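strain	type	sequences
129S1/SvImJ	IGKV	91
129S1/SvImJ	IGLV	3
A/J	IGKV	102
A/J	IGLV	3
AKR/J	IGKV	85
AKR/J	IGLV	3
BALB/c	IGHV	164
BALB/c/ByJ	IGLV	3
BALB/c/ByJ	IGKV	98
C3H/HeJ	IGKV	96
C3H/HeJ	IGLV	3
C57BL/6	IGHV	102
C57BL/6J	IGKV	91
C57BL/6J	IGLV	3
CAST/EiJ	IGKV	88
CAST/EiJ	IGLV	9
CBA/J	IGKV	82
CBA/J	IGLV	3
DBA/1J	IGKV	104
DBA/1J	IGLV	3
DBA/2J	IGKV	100
DBA/2J	IGLV	3
LEWES/EiJ	IGKV	87
LEWES/EiJ	IGLV	4
MRL/MpJ	IGKV	72
MRL/MpJ	IGLV	3
MSM/MsJ	IGKV	83
MSM/MsJ	IGLV	5
NOD/ShiLtJ	IGKV	62
NOD/ShiLtJ	IGLV	3
NOR/LtJ	IGKV	80
NOR/LtJ	IGLV	3
NZB/BlNJ	IGKV	105
NZB/BlNJ	IGLV	3
PWD/PhJ	IGKV	89
PWD/PhJ	IGLV	3
SJL/J	IGKV	67
SJL/J	IGLV	3
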