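sv_id	insertion_af
sv1	0.5
sv2	0.96
sv3	0.8
sv4	0.1
sv5	0.25
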