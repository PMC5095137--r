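# Managed-type registry.
#
# A registry maps a type name to its spec factory, its populate procedure
# (which fills a freshly created object so that it is compliant from the
# start), and an optional base type. Inheritance chains must be acyclic;
# the type filter of find_managed_objects() matches subtypes by default.

new_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "neurofmt_registry")
}

.neurofmt_registry <- new_registry()

#' The package-level managed type registry
#'
#' Holds the built-in electrophysiology types (`BrainDataFile`,
#' `BrainDataEphys`, `BrainDataEphysProcessed`, `BrainDataMultiFile`,
#' `BrainDataCollection`, `ManagedObjectContainer`) plus any types
#' registered by the user.
#'
#' @return The registry (an environment with reference semantics).
#' @export
default_registry <- function() .neurofmt_registry

#' Register a managed object type
#'
#' @param name Unused type name.
#' @param spec_factory Zero-argument function returning the type's basic
#'   (meta-valid) specification.
#' @param populate Function `(handle, payload, registry)` creating every
#'   required child of a fresh object; may be `NULL` for purely structural
#'   types.
#' @param base Optional name of an already-registered base type; derived
#'   specs extend their base (members may be specialized).
#' @param kind `"group"` or `"file"`.
#' @param registry Registry to register into.
#' @return The registry entry, invisibly.
#' @export
register_managed_type <- function(name, spec_factory, populate = NULL,
                                  base = NULL, kind = "group",
                                  registry = default_registry()) {
  stopifnot(is.character(name), nzchar(name), is.function(spec_factory))
  if (registry_has(registry, name))
    stop(sprintf("managed type '%s' is already registered", name))
  if (!is.null(base) && !registry_has(registry, base))
    stop(sprintf("base type '%s' is not registered", base))
  spec <- spec_factory()
  rep <- validate_spec_document(spec)
  if (nrow(rep) > 0)
    stop(sprintf("spec factory for '%s' produced an invalid spec: %s",
                 name, paste(rep$message, collapse = "; ")))
  entry <- list(name = name, spec_factory = spec_factory,
                populate = populate, base = base, kind = kind)
  assign(name, entry, envir = registry)
  invisible(entry)
}

registry_has <- function(registry, name) {
  !is.null(name) && exists(name, envir = registry, inherits = FALSE)
}

registry_entry <- function(registry, name) {
  if (!registry_has(registry, name))
    stop(sprintf("unknown managed type '%s'", name))
  get(name, envir = registry, inherits = FALSE)
}

registry_spec <- function(registry, name) {
  registry_entry(registry, name)$spec_factory()
}

registry_types <- function(registry) ls(registry)

# base-first chain, e.g. c("BrainDataEphys", "BrainDataEphysProcessed")
registry_base_chain <- function(registry, name) {
  chain <- name
  repeat {
    b <- registry_entry(registry, chain[1])$base
    if (is.null(b)) break
    if (b %in% chain) stop("cyclic inheritance chain at ", b)
    chain <- c(b, chain)
  }
  chain
}

# does `type` equal `of` or derive from it?
registry_is_subtype <- function(registry, type, of) {
  if (!registry_has(registry, type)) return(identical(type, of))
  of %in% registry_base_chain(registry, type)
}
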