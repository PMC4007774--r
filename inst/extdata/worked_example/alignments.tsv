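terminology_id	code	icon_id	provenance
mesh	D013966	icon_mesh_subacute_thyroiditis	manual
icd10	E06.1	icon_icd_subacute_thyroiditis	manual
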