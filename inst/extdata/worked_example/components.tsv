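component_id	name	required	multi_valued
central_color	Central color	1	0
shape	Shape	1	1
central_pictogram	Central pictogram	0	1
topright_color	Top-right color	0	0
topright_pictogram	Top-right pictogram	0	0
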