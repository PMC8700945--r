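node_a	node_b	type
HMGN1	HIST1H4A	physical
HMGN2	HIST1H2BA	physical
HMGN2	HIST1H3A	physical
HMGN2	HIST1H2AG	physical
HMGN2	HIST1H1A	proximity
HMGN3	HIST1H4A	physical
HMGN4	HIST1H2AG	physical
HMGN4	HIST1H3A	proximity
HMGN4	HIST2H2AB	physical
HMGN5	HIST1H4A	physical
HMGN1	HMGN2	coexpression
HMGN1	HIST1H4A	coexpression
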