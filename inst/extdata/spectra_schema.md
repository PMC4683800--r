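# Spectral table schema (wide CSV)

UTF-8, comma delimiter, `.` decimal separator, `NA` for missing values.

| column | type | meaning |
|---|---|---|
| sample_id | string | unique sample identifier |
| phase | int | extraction phase, 1 / 2 / 3 |
| time_min | double | sampling time, minutes into the phase |
| temperature_c | double | extract temperature (deg C), NA if unrecorded |
| `<wavelength>` ... | double | one column per grid point; header is the wavelength in nm |

Wavelength headers must be strictly increasing and uniformly spaced; the
grid is half-open `[start, stop)`, so 800-2200 nm at 0.5 nm has 2800
columns (800, 800.5, ..., 2199.5).
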