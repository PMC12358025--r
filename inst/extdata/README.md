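Synthetic example dataset (generated by the package's own simulator,
`sim_spec(K_true = 2, n_per_pop = 6, n_dominant = 6, n_codominant = 3,
drift_F = 0.25, master_seed = 2026)`): 12 accessions from two drifted
populations, a 6 dominant + 3 codominant marker panel, accession metadata,
CAPS cytoplasm pattern calls and the matching three-marker typing key.
The key illustrates the YAML schema; its fragment-pattern labels and
tuple-to-type mapping are synthetic, not a published diagnostic key.
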