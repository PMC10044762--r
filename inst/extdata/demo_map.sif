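Ddx58	activates	Il6
Il6	activates	Tnf
Tnf	activates	Nos2
Nos2	activates	Il6
Tnf	activates	NETosis
Nos2	activates	NETosis
Ptgs2	activates	NETosis
Il6	inhibits	NETosis
Fpr2	activates	Efferocytosis
Il10	activates	Efferocytosis
Hif1a	activates	Hk2
Hk2	activates	Efferocytosis
Tnf	inhibits	Efferocytosis
Il2rb	activates	Il10
Cxcr6	activates	Il2rb
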