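label	x	y	z	amplifier
AF3	-0.5023188741	0.7534783112	0.4242006404	2
AF4	0.5023188741	0.7534783112	0.4242006404	2
AF7	-0.8000000000	0.6000000000	0.0000000000	2
AF8	0.8000000000	0.6000000000	0.0000000000	2
C1	-0.3090169944	0.0000000000	0.9510565163	2
C2	0.3090169944	0.0000000000	0.9510565163	2
C3	-0.5877852523	0.0000000000	0.8090169944	1
C4	0.5877852523	0.0000000000	0.8090169944	1
C5	-0.8090169944	0.0000000000	0.5877852523	2
C6	0.8090169944	0.0000000000	0.5877852523	2
CP1	-0.3039253683	-0.3039253683	0.9029167963	1
CP2	0.3039253683	-0.3039253683	0.9029167963	1
CP3	-0.5779016055	-0.2889508028	0.7632412252	2
CP4	0.5779016055	-0.2889508028	0.7632412252	2
CP5	-0.7949195678	-0.2649731893	0.5457949154	1
CP6	0.7949195678	-0.2649731893	0.5457949154	1
CPz	0.0000000000	-0.3090169944	0.9510565163	2
Cz	0.0000000000	0.0000000000	1.0000000000	1
F1	-0.2889508028	0.5779016055	0.7632412252	2
F2	0.2889508028	0.5779016055	0.7632412252	2
F3	-0.5488386397	0.5488386397	0.6305174821	1
F4	0.5488386397	0.5488386397	0.6305174821	1
F5	-0.7534783112	0.5023188741	0.4242006404	2
F6	0.7534783112	0.5023188741	0.4242006404	2
F7	-0.8821566590	0.4410783295	0.1650743358	1
F8	0.8821566590	0.4410783295	0.1650743358	1
FC1	-0.3039253683	0.3039253683	0.9029167963	1
FC2	0.3039253683	0.3039253683	0.9029167963	1
FC3	-0.5779016055	0.2889508028	0.7632412252	2
FC4	0.5779016055	0.2889508028	0.7632412252	2
FC5	-0.7949195678	0.2649731893	0.5457949154	1
FC6	0.7949195678	0.2649731893	0.5457949154	1
FCz	0.0000000000	0.3090169944	0.9510565163	1
Fp1	-0.2333904609	0.9335618435	0.2720131928	1
Fp2	0.2333904609	0.9335618435	0.2720131928	1
Fpz	0.0000000000	0.9510565163	0.3090169944	2
FT7	-0.9335618435	0.2333904609	0.2720131928	2
FT8	0.9335618435	0.2333904609	0.2720131928	2
Fz	0.0000000000	0.5877852523	0.8090169944	1
O1	-0.2333904609	-0.9335618435	0.2720131928	1
O2	0.2333904609	-0.9335618435	0.2720131928	1
Oz	0.0000000000	-0.9510565163	0.3090169944	1
P1	-0.2889508028	-0.5779016055	0.7632412252	2
P2	0.2889508028	-0.5779016055	0.7632412252	2
P3	-0.5488386397	-0.5488386397	0.6305174821	1
P4	0.5488386397	-0.5488386397	0.6305174821	1
P5	-0.7534783112	-0.5023188741	0.4242006404	2
P6	0.7534783112	-0.5023188741	0.4242006404	2
P7	-0.8821566590	-0.4410783295	0.1650743358	1
P8	0.8821566590	-0.4410783295	0.1650743358	1
PO3	-0.5023188741	-0.7534783112	0.4242006404	2
PO4	0.5023188741	-0.7534783112	0.4242006404	2
PO7	-0.8000000000	-0.6000000000	0.0000000000	2
PO8	0.8000000000	-0.6000000000	0.0000000000	2
POz	0.0000000000	-0.8090169944	0.5877852523	2
Pz	0.0000000000	-0.5877852523	0.8090169944	1
T7	-0.9510565163	0.0000000000	0.3090169944	1
T8	0.9510565163	0.0000000000	0.3090169944	1
TP7	-0.9335618435	-0.2333904609	0.2720131928	2
TP8	0.9335618435	-0.2333904609	0.2720131928	2
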