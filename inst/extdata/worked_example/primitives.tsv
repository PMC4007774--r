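primitive_id	label	component_id	parent_id
current_condition	Current condition	central_color	ROOT
disease	Disease	shape	ROOT
inflammation	Inflammation	shape	disease
endocrine_system	Endocrine system	central_pictogram	ROOT
thyroid	Thyroid	central_pictogram	endocrine_system
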