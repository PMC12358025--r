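id	region_group	seed_length_mm	seed_width_mm	horticultural_group
ACC001	Pop1	6.09640938518679	2.1402239564448	NA
ACC002	Pop1	6.29237567741298	2.28141271154596	NA
ACC003	Pop1	3.42749013285913	1.21215814994641	NA
ACC004	Pop1	7.8977369352444	3.2609308217022	NA
ACC005	Pop1	8.18622930229054	3.37413347080564	NA
ACC006	Pop1	6.00187933313248	2.15133106086997	NA
ACC007	Pop2	10.1268371968011	3.84846675701868	NA
ACC008	Pop2	9.28278608510863	4.28060383798908	NA
ACC009	Pop2	11.200566690308	4.81631284716966	NA
ACC010	Pop2	10.8908582439863	4.39669905173498	NA
ACC011	Pop2	9.40271804278856	4.37374154557284	NA
ACC012	Pop2	12.1692963485595	5.04144353611738	NA
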