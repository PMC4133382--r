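protein_id	position
SYNPROT0001	11
SYNPROT0002	32
SYNPROT0003	32
SYNPROT0004	11
SYNPROT0005	32
SYNPROT0006	32
SYNPROT0007	32
SYNPROT0008	32
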