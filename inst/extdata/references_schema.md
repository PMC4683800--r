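# Reference table schema (long CSV)

UTF-8, comma delimiter, `NA` for missing assay values.

| column | type | meaning |
|---|---|---|
| sample_id | string | matches a spectral-table sample_id |
| analyte | string | glycyrrhizic_acid, liquiritin, isoliquiritin or total_flavonoids |
| concentration_mg_per_ml | double | reference concentration (mg/mL), >= 0 or NA |
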