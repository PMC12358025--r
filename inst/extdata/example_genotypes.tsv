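accession	R001	R002	R003	R004	R005	R006	S001	S002	S003
ACC001	0/0	1/1	1/1	0/0	0/0	0/0	5/5	5/8	1/2
ACC002	0/0	1/1	0/0	1/1	0/0	0/0	5/5	5/8	1/2
ACC003	0/0	1/1	1/1	0/0	0/0	0/0	5/5	1/8	1/2
ACC004	0/0	1/1	0/0	0/0	0/0	0/0	5/5	8/8	2/2
ACC005	0/0	1/1	1/1	0/0	0/0	0/0	5/5	7/8	1/2
ACC006	0/0	1/1	1/1	0/0	0/0	0/0	2/5	8/8	2/3
ACC007	0/0	1/1	0/0	1/1	0/0	1/1	1/2	1/5	1/1
ACC008	0/0	1/1	0/0	0/0	0/0	1/1	2/2	5/5	3/4
ACC009	0/0	1/1	1/1	0/0	0/0	0/0	1/2	5/5	1/3
ACC010	0/0	1/1	1/1	0/0	0/0	0/0	1/7	5/5	1/3
ACC011	0/0	1/1	1/1	1/1	0/0	0/0	1/5	5/5	1/1
ACC012	0/0	1/1	0/0	1/1	0/0	0/0	4/5	5/7	1/2
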