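neutrophils	synthetic demo marker set	S100a8	S100a9	Ly6g	Mpo
macrophages	synthetic demo marker set	Adgre1	Cd68	Mrc1	Csf1r
t_cells	synthetic demo marker set	Cd3e	Cd8a	Cd4	Lck
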