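id	label	node_class	submaps	phase
Ddx58	DExD/H-box helicase 58	gene	initiation
Il6	interleukin 6	gene	initiation;transition
Tnf	tumor necrosis factor	gene	initiation
Nos2	nitric oxide synthase 2	gene	initiation
Ptgs2	prostaglandin-endoperoxide synthase 2	gene	initiation
Fpr2	formyl peptide receptor 2	gene	resolution
Il10	interleukin 10	gene	resolution
Hif1a	hypoxia inducible factor 1 alpha	gene	transition
Hk2	hexokinase 2	gene	transition
Il2rb	interleukin 2 receptor beta	gene	resolution
Cxcr6	C-X-C motif chemokine receptor 6	gene	resolution
NETosis	NETosis	phenotype		initiation
Efferocytosis	apoptotic cell clearance	phenotype		resolution
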