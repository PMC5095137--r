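# neurofmt

Specification-driven HDF5 data standards for neurophysiology, in R.

Multi-modal neuroscience experiments produce many related arrays — raw
multi-electrode voltage traces, processed time–frequency bands, stimulus
schedules, derived images — whose structure and inter-relationships are
usually implicit. `neurofmt` makes both explicit:

* **A format-specification language.** Files, groups, datasets,
  attributes, and dimension scales are described by hierarchical,
  JSON-serializable specification documents built incrementally in code.
  Specifications are *minimal*: everything specified must be present and
  conforming, but users may always add custom objects without breaking
  compliance.
* **Managed objects.** An HDF5 file/group carrying four standardized
  descriptor attributes (`MANAGED_TYPE`, `MANAGED_DESCRIPTION`,
  `MANAGED_SPEC`, `MANAGED_OBJECT_ID`). Managed types are registered with
  a spec factory and a populate procedure, so objects are compliant from
  the moment they exist, can be re-wrapped by stored type, verified at any
  time, and stored either in-file or in external files behind HDF5
  external links — transparently.
* **Relationship attributes.** JSON-valued attributes
  (`RELATIONSHIP_ATTR_<name>`) on a source object declaring a typed link
  `R[A→B]` to a target. Seven types (`order`, `equivalent`, `indexes`,
  `shared_encoding`, `shared_ascending_encoding`, `indexes_values`,
  `user`); every type except `user` implies a rule for mapping element
  selections from source to target, e.g. `B[R[A→B][sel]]` reads the
  target values matching a source selection.
* **Index map relationships (IMR).** A chain of relationship attributes —
  `order` A→M, `order` M→A, `indexes` M→B, optional `user` A→B, under one
  base name with reserved `_IMR_*` postfixes — routing selections from A
  through an explicit index map M into B. Supports arbitrary N-to-M
  correspondences (stacking axis with −1 sentinels), e.g. pixel-to-block
  image registration.
* **An electrophysiology application format.** `BrainDataFile` session
  files (`/data/{internal,external}`, `/descriptors/{static,dynamic}`),
  `BrainDataEphys` groups (2-D space × time voltage arrays in Volts,
  electrode-id/time/anatomy dimension scales, time in ms generated as
  `t_k = start_time + 1000·k/rate`, auto-expanding acquisition mode),
  `BrainDataEphysProcessed` (space × time × band), device collections,
  and multi-session container files.
* **Synthetic fixtures** for end-to-end testing without any external
  data, plus a violation injector for exercising the verifier, and a
  small CLI (`validate`, `inspect`, `spec`, `map-selection`, `demo`).

## Worked example

```r
library(neurofmt)

f <- tempfile(fileext = ".h5")
session <- create_session_file(f)
internal <- wrap_managed_object(f, "/data/internal")
set.seed(1)
raw <- create_ephys(internal, "grid",
                    raw = matrix(rnorm(4 * 100, sd = 1e-4), 4, 100),
                    sampling_rate = 12200, electrode_ids = 0:3)
raw
#> <managed BrainDataEphys> /data/internal/ephys_data_grid in /tmp/...h5
verify_compliance(raw)
#> <compliance report> COMPLIANT, 0 finding(s)
ephys_aux(raw, "sampling_rate")
#> [1] 12200
head(ephys_aux(raw, "time")$data, 3)        # ms, = 1000 * k / 12200
#> [1] 0.00000000 0.08196721 0.16393443
```

Every dimension scale automatically carries an `order` relationship to
the data it describes; selections map through it (0-based, half-open):

```r
rel <- find_relationships(
  wrap_managed_object(f, file.path(raw$path, "time")),
  file.path(raw$path, "raw_data"))[[1]]
map_selection(rel, selection(sel_range(10, 20)))
#> <selection> [10,20)
```

An index map relationship describing a 120×122 image whose every pixel
corresponds to a 5×5 block of a 5×-resolution (axis-swapped) 610×600
image; mapping source pixel `[36, 70]` selects the matching block:

```r
g <- tempfile(fileext = ".h5")
imr <- generate_image_scaling_fixture(image_map_params(120, 122, 5), g)
imr
#> <index map relationship 'scaling'> /A -> /M -> /B (legs: SOURCE_TO_MAP, MAP_TO_SOURCE, MAP_TO_TARGET)
ps <- imr_map(imr, "MAP_TO_TARGET", selection(sel_point(36), sel_point(70)))
ps
#> <point-set selection> 25 point(s), rank 2
pointset_block(ps)$bounds                    # rows 350..354, cols 180..184
#>      [,1] [,2]
#> [1,]  350  180
#> [2,]  354  184
```

The 25 selected pixels form the full 5×5 block at the transposed, scaled
position — the source pixel's row 36 lands on target columns
`36·5 … 36·5+4` and its column 70 on target rows `70·5 … 70·5+4`.

## Command line

```sh
inst/cli/neurofmt validate session.h5            # exit 0 iff compliant
inst/cli/neurofmt inspect session.h5 --relationships
inst/cli/neurofmt spec BrainDataEphys --recursive
inst/cli/neurofmt map-selection img.h5 --source /A --leg MAP_TO_TARGET --sel 36,70
inst/cli/neurofmt demo imagemap --out img.h5
```

See `vignettes/neurofmt-methods.Rmd` for the data model, mapping rules,
numerical conventions, and design rationale.
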