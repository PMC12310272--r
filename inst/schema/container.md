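# Session container schema (version 1.0)

A recording container is a directory with two files:

## `meta.json`

| field | type | units / values |
|---|---|---|
| `schema_version` | string | `"1.0"` |
| `recording.rate` | number | Hz |
| `recording.t0` | number | s, trace start |
| `recording.phase` | string | `baseline`, `post_tetanic`, `io_sweep` |
| `recording.n_rows`, `recording.n_cols` | integer | grid extent |
| `recording.pitch_um` | number | um |
| `recording.n_samples` | integer | samples per channel |
| `recording.events.time` | number[] | s within the trace |
| `recording.events.intensity` | number[] | uA |
| `recording.events.half_width_us` | number[] | us (70-140) |
| `recording.events.site_x`, `.site_y` | number[] | um |
| `recording.events.kind` | string[] | `test_pulse`, `hfs_train` |
| `recording.events.nominal_min` | number[] | protocol minutes relative to HFS |
| `layers.labels` | string[] | one per electrode, row-major channel order |
| `layers.network` | string | `CA`, `DG`, `mixed` |
| `ground_truth` | object or null | generator ground truth, if any |

Readers must reject any other `schema_version` rather than reinterpret.

## `voltages.f64`

Raw little-endian IEEE-754 float64, column-major `channels x samples`
matrix (channel index fastest), microvolts. The byte size must equal
`8 * n_rows * n_cols * n_samples`; anything else is a truncation error.

Channels are row-major on the grid: channel 1 is the top-left electrode
(row 1, col 1), coordinates `x = (col-1)*pitch`, `y = (row-1)*pitch`.

A session directory contains one such container per recorded phase
(`io_sweep/`, `baseline/`, `post_tetanic/`); the layer map is stored with
every phase and the ground truth with the first.
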