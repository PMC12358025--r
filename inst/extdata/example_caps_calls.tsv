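accession	Cp1	Cp2	Cp3
ACC001	420	510	390
ACC002	420	510	390
ACC003	420	510	390
ACC004	420	510	390
ACC005	420	510	390
ACC006	420	510	390
ACC007	420	350+160	390
ACC008	420	350+160	390
ACC009	420	350+160	390
ACC010	420	350+160	390
ACC011	420	350+160	390
ACC012	420	350+160	390
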