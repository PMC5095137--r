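---
title: "neurofmt: data model, mapping rules, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neurofmt: data model, mapping rules, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofmt)
```

# The problem

Neurophysiology experiments produce collections of HDF5 arrays whose
organization and mutual relationships are conventionally implicit: a
time scale is *assumed* to be ordered like the axis it describes, a
stimulus table is *assumed* to reference a recording's samples, a
processed band array is *assumed* to align with its raw source. `neurofmt`
provides three layers that make these conventions formal, verifiable, and
machine-usable: a specification language for format components, managed
HDF5 objects governed by those specifications, and typed relationship
attributes with defined selection-mapping semantics.

# Specification language

A specification document is a tree of nodes (group, dataset, attribute,
dimension scale, managed reference, relationship), each carrying a `kind`
discriminator so that documents survive a JSON round trip losslessly.
Child objects are addressed by an exact `name` *or* a `prefix`; exactly
one of the two must be given. Prefix matching is plain "starts with" —
the simplest rule that keeps matching unambiguous; no richer pattern
language is attempted.

Compliance semantics are *minimal*: every specified object must be
present and conforming (honoring fixed attribute values, dimension-scale
attachment and lengths, required relationship attributes, and managed
children recursively), but unspecified extra objects never produce
findings. This is what lets users store instrument-specific metadata in
standard files without losing compliance, and it is property-tested:
random additions to compliant files must never introduce an error
finding. The one deliberate exception is a *broken external link*, which
always yields an error: a link whose target file has disappeared is
corruption of existing structure, not an "extra object".

Two compilation modes exist. `compile_recursive_spec()` inlines every
managed reference, producing a self-contained document (cyclic type
references are a hard error — a recursive document must be finite).
`compile_format_document()` lists each registered type's *basic* spec
without inlining, so it tolerates cyclic type graphs. Basic specs are
strictly smaller than the recursive root spec whenever the root
references other types; this is asserted as a size inequality, not a
line count.

# Managed objects

A managed object stores four descriptors as reserved HDF5 attributes:
`MANAGED_TYPE`, `MANAGED_DESCRIPTION`, `MANAGED_SPEC` (the JSON of the
basic spec), and optional `MANAGED_OBJECT_ID`. Storing the full spec —
not just the type name — makes files self-describing even where the
reading side lacks the type registry; the registry spec is the fallback
when only the type name is present.

Creation is atomic: the group is created, descriptors written, the
type's populate procedure run, and compliance verified; any failure
deletes the partial object before the error propagates. Objects
therefore never exist in an invalid state — the package-wide
creation-implies-compliance property.

**Inheritance.** Registered types may name a base type; type filters
match subtypes by default (an `exact` flag disables this). The built-in
processed-recording type illustrates a deliberate specialization: it
inherits the raw type's auxiliary structure (sampling rate, electrode
and time scales) but its primary dataset is the rank-3 `data` array
rather than the rank-2 `raw_data`. A strict "derived spec is a superset
of the base spec" rule cannot accommodate this replacement of the
primary dataset, so inheritance here means *extension with
specialization*: auxiliary members are inherited, the primary dataset
may be substituted, and subtype search relies on the registry's base
chain rather than on structural subsumption.

**Modular storage.** A managed object may live in an external HDF5 file
(a one-object `ManagedObjectContainer`) linked into its parent. All
discovery, verification, and mapping operations address objects through
the parent file's paths, so internal and external storage are
observationally identical — including compliance reports. To make this
hold for relationships, the automatically created scale-to-data links
store *sibling-relative* target locations (just the dataset name,
resolved against the source's parent group): an absolute path written
inside the member file would not match the path seen through the
external link. User-created relationships may use absolute in-file
paths or `list(file=, path=)` for cross-file targets.

Multi-file containers hold `/entry_0, /entry_1, …` external links to
member session roots, numbered densely in insertion order.

# Relationship attributes and selection mapping

A relationship is stored on its source object as the attribute
`RELATIONSHIP_ATTR_<name>` whose value is a self-contained JSON
document: type, description, free-form properties, the source axes it
applies to, and the target location and axes. Seven types are defined;
their mapping rules for a selection `s` on the source are:

| type | mapped selection on the target |
|---|---|
| `order`, `equivalent` | the same element indices (groups: same ordinals in alphabetic member order) |
| `indexes` | the index values stored in the source at the selected positions |
| `shared_encoding`, `indexes_values` | all target positions whose value equals any selected source value |
| `shared_ascending_encoding` | range selections: all target positions with value in `[min, max]` of the selected source values; point selections: exact value match |
| `user` | none — mapping is an error by definition |

Conventions, stated once and used everywhere: indices are 0-based,
ranges half-open `[start, stop)`. Mapped selections are deduplicated and
ascending; a contiguous 1-D result is expressed as a range, otherwise as
an index list; multi-dimensional results are point sets
(`pointset_block()` summarizes rectangular ones). Value matching is
exact equality only — no floating-point tolerance; for float-valued
scales (e.g. two time axes with different sampling rates) the
recommended type is `shared_ascending_encoding`, whose range semantics
compare only minima and maxima. Point selections under that type fall
back to exact matching: without a range there is no interval to compare,
and silently widening a point to a tolerance window would invent a
parameter the data does not declare. Ascending order of stored values is
trusted, not re-verified, at mapping time.

An empty value-match result is an empty selection, not an error;
out-of-bounds indices are errors.

# Index map relationships

Where a direct rule cannot express a correspondence (registration,
rescaling, arbitrary N-to-M links), an explicit index map `M` stores,
for each source element of `A`, the indices of its corresponding
elements in `B`. The chain is realized as relationship attributes under
one base name with reserved postfixes: `_IMR_SOURCE_TO_MAP` (`order`,
on A), `_IMR_MAP_TO_SOURCE` (`order`, on M), `_IMR_MAP_TO_TARGET`
(`indexes`, on M), and — only when user properties are supplied —
`_IMR_SOURCE_TO_TARGET` (`user`, on A). Creation is atomic across legs.
`imr_map(imr, "SOURCE_TO_TARGET", s)` is *defined* as the composition
of the order leg and the indexes leg; the user leg never maps.

The index-map layout is rectangular: spatial axes of the source, then an
index axis (one slot per target axis), then a stacking axis sized to the
maximum multiplicity, with unused slots filled by the sentinel −1 and
dropped during mapping. A 1-D target needs no index axis; the
disambiguation rule is: one extra axis beyond the spatial axes is a
stacking axis when the target is 1-D, an index axis otherwise. Mapping
results are deduplicated ascending, so N-to-M maps lose no stored
(source, target) pair — asserted against an oracle that reads the map
array directly.

Bundle discovery (`get_index_map_relationships()`) groups co-named
postfixed attributes from either end of the chain (source or map);
bundles missing a required leg are reported as findings, not returned.

# The electrophysiology format

Session files separate `/data` from `/descriptors`, internal (in-brain)
from external recordings, and static from dynamic metadata; these
concrete paths are this package's choice — the concepts, not the names,
are the contract. Raw recordings are 2-D space × time arrays with a
fixed `unit = "Volt"` attribute; the sampling rate is its own scalar
dataset in Hz; the time scale is in milliseconds,
`t_k = start_time + 1000·k/rate`, hence strictly increasing whenever
generated. Scales follow the HDF5 dimension-scale convention (visible
to h5py/h5dump) and carry their five-field record (data, unit,
description, name, axis) as attributes. Voltages are stored as 64-bit
floats in the fixtures; any numeric dtype is accepted, the unit
attribute being mandatory.

Auto-expand mode creates the time axis empty and extendible (chunked
storage, full-space × bounded-time slabs); `append_recordings()`
validates every time-axis scale *before* touching the file, so a
refused append leaves all extents unchanged — axis-length conservation
is the tested invariant. Appended values for custom time-axis scales
must be supplied by the caller; the built-in time scale continues its
series.

Processed groups (space × time × band) link back to their raw source
with an `order` relationship on the shared space axis and a
`shared_ascending_encoding` relationship between the two time scales,
which is exactly what allows extracting matching raw/processed windows
under differing sampling rates.

# Synthetic fixtures: what they emulate and what they do not

`generate_ephys_session()` emulates the *structure* of a dual-device
tone-mapping experiment: a 16-electrode surface grid and a 4-site
polytrode at 12 200 Hz, tone conditions spanning 0.5–32 kHz at
attenuations 0…−70 dB, each presented 20 times for 300 ms (the default
parameter set; the recording length is their product). Signals are
per-electrode sinusoids plus Gaussian noise at ~10⁻⁴ V — chosen only to
make demonstration plots legible; no physiological claim is made, and no
spectral content, response statistics, or real mass-spectrometry data
are emulated. Green tests on these fixtures establish the *mechanics* —
compliance, discovery, mapping, expansion — not scientific validity of
any analysis. Stimulus onsets are stored as onset times in
milliseconds whose values coincide with time-scale entries, so the
declared `indexes_values` (value-matching) relationship into the time
scale is semantically exact; onsets-as-sample-indices would instead
require an `indexes` relationship.

The image-scaling fixture reproduces a pixel-to-block correspondence: a
`rows × cols` source, a `(cols·f) × (rows·f)` target (the axis-swap
convention: source axis 0 maps to target axis 1 and vice versa), and a
4-D index map `(rows, cols, 2, f²)`. With the default 120×122 source
and factor 5, mapping the single pixel `[36, 70]` through
`MAP_TO_TARGET` selects the full 5×5 block at target rows 350–354 ×
columns 180–184 — the package's headline acceptance check, which the
test suite and `scripts/acceptance.R` both recompute from scratch.

The default session parameters describe an acquisition-scale recording
(minutes of multi-channel data); the test suite passes reduced
parameter sets (fewer conditions and repetitions, lower rate) purely
for runtime. Structure — two devices, raw + processed per device,
stimulus schedule and its relationships — is identical at every scale.

# Numerical and implementation notes

* HDF5 access goes through a minimal bundled C binding (open–act–close
  per operation; files at this scale make handle caching unnecessary).
  R's column-major dim order is reversed at the HDF5 boundary, so data
  never needs transposition; a 4×100 R matrix appears as a 100×4
  dataset to row-major tools.
* JSON serialization uses stable key ordering; numbers round-trip as
  doubles (JSON does not distinguish integer from double storage, and
  neither does document equality).
* Group `order` relationships use lexicographic byte order of member
  names.
* Relationship creation verifies that the target resolves; an explicit
  `allow_dangling` flag permits staged file assembly, with verification
  reporting a warning rather than an error.
* Equal mapped indices arising from different stacking slots are
  deduplicated; mapping is therefore idempotent on its result.

# Known limitations

* No in-place migration between spec versions, no repacking utilities.
* No transitive closure over arbitrary relationship chains beyond the
  index-map pattern; no automatic image registration (index maps are
  inputs).
* Value matching offers no floating-point tolerance by design; use
  `shared_ascending_encoding` ranges for float scales.
* Compliance checking reads whole scale datasets for length checks;
  this is appropriate for metadata-scale arrays, not multi-gigabyte
  scales.
* The CLI covers validation, inspection, spec export, mapping, and demo
  generation; it is not an interactive shell and has no plotting.
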