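icon_id	component_id	primitive_id
icon_mesh_subacute_thyroiditis	central_color	current_condition
icon_mesh_subacute_thyroiditis	shape	disease
icon_mesh_subacute_thyroiditis	central_pictogram	endocrine_system
icon_icd_subacute_thyroiditis	central_color	current_condition
icon_icd_subacute_thyroiditis	shape	disease
icon_icd_subacute_thyroiditis	shape	inflammation
icon_icd_subacute_thyroiditis	central_pictogram	thyroid
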