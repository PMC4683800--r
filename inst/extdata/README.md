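# Shipped plain-text data

- `published_phase_relative_errors.csv` - per-sample relative errors (%) of
  the NIR predictions against the reference assay in the three extraction
  phases, as printed in the published phase-wise assessment table of the
  study this package's workflow follows. `NA` marks samples that were not
  selected into the validation set for that analyte ("NA samples"). The
  second-phase row `o` is printed with a duplicated label in the source
  table; it is relabelled here.
- `published_phase_mean_relative_errors.csv` - the per-phase mean relative
  errors as printed. Note: the phase-1 row (all analytes) and the phase-2
  row (all but glycyrrhizic acid) equal the means of the per-sample columns
  at 2 decimals; the remaining printed averages do not match their own
  columns (phase-2 glycyrrhizic acid 4.42 vs recomputed 4.43; all phase-3
  entries). This package reproduces the arithmetic, not the misprints.
- `spectra_schema.md` / `references_schema.md` - file-format schemas for the
  delimited-text spectral and reference tables.
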