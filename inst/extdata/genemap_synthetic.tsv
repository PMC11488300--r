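synthetic_id	gene_symbol	note
G000001	DDX58	documentation-only mapping; synthetic ids carry no biology
G000002	IRF7	documentation-only mapping; synthetic ids carry no biology
G000003	ISG15	documentation-only mapping; synthetic ids carry no biology
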