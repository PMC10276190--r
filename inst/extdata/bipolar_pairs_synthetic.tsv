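# Synthetic stand-in bipolar pair table (the published 112-pair scheme is
# not printed): the 112 closest electrode pairs on a planar 10-10 grid.
# Columns: anode cathode virtual
anode	cathode	virtual
C1	C3	C1-C3
C1	Cz	C1-Cz
C2	C4	C2-C4
C2	Cz	C2-Cz
C3	C5	C3-C5
C4	C6	C4-C6
C5	T7	C5-T7
C6	T8	C6-T8
CP1	C1	CP1-C1
CP1	CP3	CP1-CP3
CP1	CPz	CP1-CPz
CP1	P1	CP1-P1
CP2	C2	CP2-C2
CP2	CP4	CP2-CP4
CP2	CPz	CP2-CPz
CP2	P2	CP2-P2
CP3	C3	CP3-C3
CP3	CP5	CP3-CP5
CP3	P3	CP3-P3
CP4	C4	CP4-C4
CP4	CP6	CP4-CP6
CP4	P4	CP4-P4
CP5	C5	CP5-C5
CP5	P5	CP5-P5
CP5	TP7	CP5-TP7
CP6	C6	CP6-C6
CP6	P6	CP6-P6
CP6	TP8	CP6-TP8
CPz	Cz	CPz-Cz
CPz	Pz	CPz-Pz
F1	F3	F1-F3
F1	Fz	F1-Fz
F2	F4	F2-F4
F2	Fz	F2-Fz
F3	AF3	F3-AF3
F3	F5	F3-F5
F4	AF4	F4-AF4
F4	F6	F4-F6
F5	F7	F5-F7
F6	F8	F6-F8
F7	AF7	F7-AF7
F7	FT7	F7-FT7
F8	AF8	F8-AF8
F8	FT8	F8-FT8
FC1	C1	FC1-C1
FC1	F1	FC1-F1
FC1	FC3	FC1-FC3
FC2	C2	FC2-C2
FC2	F2	FC2-F2
FC2	FC4	FC2-FC4
FC3	C3	FC3-C3
FC3	F3	FC3-F3
FC3	FC5	FC3-FC5
FC4	C4	FC4-C4
FC4	F4	FC4-F4
FC4	FC6	FC4-FC6
FC5	C5	FC5-C5
FC5	F5	FC5-F5
FC5	FT7	FC5-FT7
FC6	C6	FC6-C6
FC6	F6	FC6-F6
FC6	FT8	FC6-FT8
FT7	FT9	FT7-FT9
FT8	FT10	FT8-FT10
O1	Oz	O1-Oz
Oz	O2	Oz-O2
Oz	POz	Oz-POz
P1	P3	P1-P3
P1	Pz	P1-Pz
P2	P4	P2-P4
P2	Pz	P2-Pz
P3	P5	P3-P5
P4	P6	P4-P6
P5	P7	P5-P7
P6	P8	P6-P8
P7	TP7	P7-TP7
P8	TP8	P8-TP8
PO3	P3	PO3-P3
PO4	P4	PO4-P4
PO7	P7	PO7-P7
PO7	PO9	PO7-PO9
PO8	P8	PO8-P8
PO8	PO10	PO8-PO10
POz	Pz	POz-Pz
T7	FT7	T7-FT7
T7	TP7	T7-TP7
T8	FT8	T8-FT8
T8	TP8	T8-TP8
TP7	TP9	TP7-TP9
TP8	TP10	TP8-TP10
C5	FT7	C5-FT7
C5	TP7	C5-TP7
C6	FT8	C6-FT8
C6	TP8	C6-TP8
CP1	C3	CP1-C3
CP1	Cz	CP1-Cz
CP1	P3	CP1-P3
CP1	Pz	CP1-Pz
CP2	C4	CP2-C4
CP2	Cz	CP2-Cz
CP2	P4	CP2-P4
CP2	Pz	CP2-Pz
CP3	C1	CP3-C1
CP3	C5	CP3-C5
CP3	P1	CP3-P1
CP3	P5	CP3-P5
CP4	C2	CP4-C2
CP4	C6	CP4-C6
CP4	P2	CP4-P2
CP4	P6	CP4-P6
CP5	C3	CP5-C3
CP5	P3	CP5-P3
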