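terminology_id	code	label	parents	cross_ids
mesh	D013966	Thyroiditis, Subacute		C0040149
icd10	E06.1	Subacute thyroiditis		C0040149
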