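name	kind	chromosome	n_alleles
R001	dominant	NA	2
R002	dominant	NA	2
R003	dominant	NA	2
R004	dominant	NA	2
R005	dominant	NA	2
R006	dominant	NA	2
S001	codominant	NA	7
S002	codominant	NA	8
S003	codominant	NA	4
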