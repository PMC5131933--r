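# File formats

## Voltage movie container (`write_movie()` / `read_movie()`)

R native serialization (version 3), conventionally `.rds`. One list:

| field               | type            | meaning                                   |
|---------------------|-----------------|-------------------------------------------|
| `container`         | string          | always `"spiralps-movie"`                 |
| `version`           | int             | container version (1)                     |
| `frames`            | H x W x T array | transmembrane potential, mV               |
| `dx_mm`             | numeric         | pixel spacing, mm (mandatory)             |
| `frame_interval_ms` | numeric         | sampling interval, ms (mandatory)         |
| `t0_ms`             | numeric         | time of the first frame                   |
| `meta`              | list            | provenance (scenario, solver, protocol)   |

Reading a container that lacks `frames`, `dx_mm` or `frame_interval_ms`
is a hard error naming the missing field. Pixel (r, c) sits at
x = (c-1)*dx_mm, y = (r-1)*dx_mm, origin at the top-left pixel, rows
increasing downward.

## PS point sets (`write_ps_csv()` / `read_ps_csv()`)

Plain CSV preceded by one comment line `# dx_mm: <value>`. Columns:

| column      | meaning                                                   |
|-------------|-----------------------------------------------------------|
| `method`    | `iyer_gray` or `location_centric`                         |
| `frame`     | phase-frame index (1-based)                               |
| `t_ms`      | frame time, ms                                            |
| `row`,`col` | pixel indices, 1-based                                    |
| `x_mm`,`y_mm` | physical position: x=(col-1)*dx, y=(row-1)*dx           |
| `chirality` | winding sign (+1/-1) for `iyer_gray`; `NA` for the location-centric criterion |

All angles handled by the package are radians; phases lie in (-pi, pi].

## Run configuration (`read_run_config()` / `write_run_config()`)

YAML with sections `sim` (grid, duration_ms, scenario, protocol,
D_cm2_per_ms, dt bounds, sample_interval_ms, record_from_ms), `phase`
(tau_ms, vmean window), `detect` (method, M), `compare` (resolution_mm).
Unset fields take the package defaults; files round-trip losslessly
(numeric precision 15 digits).
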