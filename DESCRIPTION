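Package: neurofmt
Title: Specification-Driven HDF5 Data Standards for Neurophysiology
Version: 0.1.0
Authors@R: person("neurofmt", "developers", role = c("aut", "cre"),
    email = "maintainers@neurofmt.invalid")
Description: A framework for designing, verifying, and using formally
    specified HDF5 data standards, with an application format for
    electrophysiology recordings. Provides a JSON-serializable
    format-specification language for files, groups, datasets, attributes,
    and dimension scales; managed HDF5 objects with compliance
    verification and modular (external-link) storage; semantic
    relationship attributes with selection mapping between registered
    arrays, including chained index-map relationships; managed types for
    multi-electrode voltage recordings (ECoG grids, polytrodes) with
    dimension scales and auto-expanding acquisition; and deterministic
    synthetic fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: HDF5 (>= 1.10), including the high-level (hdf5_hl)
    dimension-scale API
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
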