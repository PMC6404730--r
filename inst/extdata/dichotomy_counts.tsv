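study_set	n_res	n_dom	n_sub	n_over	n_under
preliminary_21_gene_set	92	45	47	66	26
neuropeptidergic	97	51	46	66	31
non-neuropeptidergic	505	240	265	342	163
neurotrophinergic	506	265	241	346	160
TOTAL	1108	556	552	754	354
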