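#' Managed HDF5 objects
#'
#' A managed object is an HDF5 file, group, or dataset carrying four
#' standardized descriptor attributes: its managed type, a human-readable
#' description, the JSON text of its basic format specification, and an
#' optional unique object identifier. Managed objects are created through
#' their registered type so that they are compliant from the moment they
#' exist, can be re-wrapped by reading the stored type, and can be verified
#' against their specification at any time.
#'
#' @name managed-objects
NULL

# reserved descriptor attribute names
ATTR_MANAGED_TYPE <- "MANAGED_TYPE"
ATTR_MANAGED_DESCRIPTION <- "MANAGED_DESCRIPTION"
ATTR_MANAGED_SPEC <- "MANAGED_SPEC"
ATTR_MANAGED_OBJECT_ID <- "MANAGED_OBJECT_ID"

new_handle <- function(file, path, kind, managed_type = NULL,
                       descriptors = list(), unmanaged = is.null(managed_type)) {
  structure(list(file = file, path = path, kind = kind,
                 managed_type = managed_type, descriptors = descriptors,
                 unmanaged = unmanaged),
            class = "neurofmt_handle")
}

#' @export
print.neurofmt_handle <- function(x, ...) {
  cat(sprintf("<%s> %s in %s\n",
              if (x$unmanaged) "unmanaged object"
              else paste0("managed ", x$managed_type),
              x$path, x$file))
  invisible(x)
}

as_handle <- function(x, path = "/") {
  if (inherits(x, "neurofmt_handle")) return(x)
  if (is.character(x) && length(x) == 1) return(wrap_managed_object(x, path))
  stop("expected a managed object handle or a file path")
}

write_descriptors <- function(file, path, type_name, description, spec,
                              object_id = NULL) {
  h5_write_attr(file, path, ATTR_MANAGED_TYPE, type_name)
  h5_write_attr(file, path, ATTR_MANAGED_DESCRIPTION, description)
  h5_write_attr(file, path, ATTR_MANAGED_SPEC, spec_to_json(spec))
  if (!is.null(object_id))
    h5_write_attr(file, path, ATTR_MANAGED_OBJECT_ID, object_id)
}

read_descriptors <- function(file, path) {
  d <- list()
  for (a in c(ATTR_MANAGED_TYPE, ATTR_MANAGED_DESCRIPTION,
              ATTR_MANAGED_SPEC, ATTR_MANAGED_OBJECT_ID)) {
    if (h5_attr_exists(file, path, a)) d[[a]] <- h5_read_attr(file, path, a)
  }
  d
}

is_managed_path <- function(file, path) {
  h5_object_exists(file, path) &&
    h5_attr_exists(file, path, ATTR_MANAGED_TYPE)
}

#' Wrap an HDF5 object into a typed handle
#'
#' Dispatch is driven by the stored `MANAGED_TYPE` attribute. Objects
#' without descriptors yield a generic handle flagged `unmanaged`; objects
#' whose stored type is not registered yield a generic handle and a
#' warning.
#'
#' @param file HDF5 file path.
#' @param path HDF5 object path within the file.
#' @param registry Managed type registry.
#' @return A handle.
#' @export
wrap_managed_object <- function(file, path = "/",
                                registry = default_registry()) {
  if (!h5_is_hdf5(file)) stop("not an HDF5 file: ", file)
  if (!h5_object_exists(file, path))
    stop(sprintf("no object at '%s' in %s", path, file))
  kind <- h5_obj_kind(file, path)
  if (path == "/") kind <- "file"
  d <- read_descriptors(file, path)
  type <- d[[ATTR_MANAGED_TYPE]]
  if (is.null(type))
    return(new_handle(file, path, kind))
  if (!registry_has(registry, type)) {
    warning(sprintf("object at '%s' has unregistered managed type '%s'",
                    path, type))
    return(new_handle(file, path, kind, managed_type = NULL,
                      descriptors = d))
  }
  new_handle(file, path, kind, managed_type = type, descriptors = d)
}

# resolve the on-disk name for a new managed object from its spec's
# name/prefix rule and the user-supplied name
resolve_object_name <- function(spec, name) {
  exact <- spec_node_name(spec)
  prefix <- spec_node_prefix(spec)
  if (!is.null(exact) && exact != "/") {
    if (!is.null(name) && name != exact)
      stop(sprintf("type requires the exact name '%s'", exact))
    return(exact)
  }
  if (!is.null(prefix)) {
    if (is.null(name)) stop("type uses a name prefix; supply a name")
    if (startsWith(name, prefix)) return(name)
    return(paste0(prefix, name))
  }
  if (is.null(name)) stop("supply a name for the new object")
  name
}

#' Create a managed object
#'
#' Creates the HDF5 group, writes the four descriptor attributes, runs the
#' type's populate procedure with `payload`, and verifies compliance. On
#' any failure the partially created object is deleted before the error is
#' re-raised, so a managed object can never exist in an invalid state.
#'
#' @param parent Handle (or file path) of the parent group.
#' @param type_name Registered managed type.
#' @param name Object name; combined with the type's name prefix when the
#'   spec uses one.
#' @param payload Named list of inputs consumed by the type's populate
#'   procedure.
#' @param description Stored human-readable description.
#' @param object_id Optional unique identifier (e.g. a DOI).
#' @param registry Managed type registry.
#' @return Handle of the new object.
#' @export
create_managed_object <- function(parent, type_name, name = NULL,
                                  payload = list(), description = NULL,
                                  object_id = NULL,
                                  registry = default_registry()) {
  parent <- as_handle(parent)
  entry <- registry_entry(registry, type_name)
  spec <- entry$spec_factory()
  obj_name <- resolve_object_name(spec, name)
  path <- h5_path_join(parent$path, obj_name)
  if (h5_link_exists(parent$file, path))
    stop(sprintf("name collision: '%s' already exists", path))
  h5_create_group(parent$file, path)
  handle <- new_handle(parent$file, path, "group", managed_type = type_name)
  ok <- FALSE
  on.exit(if (!ok) try(h5_delete(parent$file, path), silent = TRUE))
  write_descriptors(parent$file, path, type_name,
                    description %||% spec$description %||% "", spec,
                    object_id)
  if (!is.null(entry$populate))
    entry$populate(handle, payload, registry)
  report <- verify_compliance(handle, registry = registry)
  if (!report$compliant)
    stop("freshly created object is non-compliant: ",
         paste(report$findings$message, collapse = "; "))
  ok <- TRUE
  wrap_managed_object(parent$file, path, registry)
}

#' Create a managed file
#'
#' A managed file is a managed object whose storage object is the file's
#' root group.
#'
#' @param path Filesystem path of the new HDF5 file.
#' @param type_name Registered managed file type.
#' @inheritParams create_managed_object
#' @param overwrite Replace an existing file?
#' @return Handle onto the file root.
#' @export
create_managed_file <- function(path, type_name, payload = list(),
                                description = NULL, object_id = NULL,
                                overwrite = FALSE,
                                registry = default_registry()) {
  entry <- registry_entry(registry, type_name)
  spec <- entry$spec_factory()
  if (file.exists(path) && !overwrite)
    stop(sprintf("file '%s' exists; use overwrite = TRUE", path))
  h5_create_file(path, overwrite = overwrite)
  handle <- new_handle(path, "/", "file", managed_type = type_name)
  ok <- FALSE
  on.exit(if (!ok) unlink(path))
  write_descriptors(path, "/", type_name,
                    description %||% spec$description %||% "", spec,
                    object_id)
  if (!is.null(entry$populate))
    entry$populate(handle, payload, registry)
  report <- verify_compliance(handle, registry = registry)
  if (!report$compliant)
    stop("freshly created file is non-compliant: ",
         paste(report$findings$message, collapse = "; "))
  ok <- TRUE
  wrap_managed_object(path, "/", registry)
}

# ---- compliance verification ----------------------------------------------

new_report <- function(findings) {
  structure(list(findings = findings,
                 compliant = !any(findings$severity == "error")),
            class = "neurofmt_compliance_report")
}

#' @export
print.neurofmt_compliance_report <- function(x, ...) {
  cat(sprintf("<compliance report> %s, %d finding(s)\n",
              if (x$compliant) "COMPLIANT" else "NON-COMPLIANT",
              nrow(x$findings)))
  if (nrow(x$findings)) print(x$findings, row.names = FALSE)
  invisible(x)
}

finding <- function(path, rule, severity, message) {
  data.frame(path = path, rule = rule, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(path = character(), rule = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Verify format compliance of an HDF5 object
#'
#' Recursively checks required child presence (honoring the name/prefix
#' rule), fixed attribute values, dimension-scale attachment and lengths,
#' presence of required relationship attributes, and compliance of managed
#' children. Specifications are minimal: objects not named in the spec
#' never cause findings; broken external links always do.
#'
#' @param x Handle, or an HDF5 file path (then `path` selects the object).
#' @param path Object path when `x` is a file path.
#' @param spec Specification to check against; defaults to the stored
#'   spec and falls back to the registered spec of the stored managed type.
#' @param registry Managed type registry.
#' @return A compliance report: `$findings` data frame (`path`, `rule`,
#'   `severity`, `message`) and `$compliant` flag. An object is compliant
#'   iff there are no error-severity findings.
#' @export
verify_compliance <- function(x, path = "/", spec = NULL,
                              registry = default_registry()) {
  h <- if (inherits(x, "neurofmt_handle")) x else {
    if (!h5_is_hdf5(x)) stop("not an HDF5 file: ", x)
    new_handle(x, path, "unknown")
  }
  if (is.null(spec)) {
    d <- read_descriptors(h$file, h$path)
    if (!is.null(d[[ATTR_MANAGED_SPEC]])) {
      spec <- spec_from_json(d[[ATTR_MANAGED_SPEC]])
    } else if (!is.null(d[[ATTR_MANAGED_TYPE]]) &&
               registry_has(registry, d[[ATTR_MANAGED_TYPE]])) {
      spec <- registry_spec(registry, d[[ATTR_MANAGED_TYPE]])
    } else {
      stop(sprintf("no resolvable specification for object '%s'", h$path))
    }
  }
  new_report(verify_node(h$file, h$path, spec, registry))
}

verify_node <- function(file, path, spec, registry) {
  f <- no_findings()
  if (!h5_object_exists(file, path)) {
    sev <- if (h5_link_exists(file, path)) "error" else "error"
    rule <- if (h5_link_exists(file, path)) "broken-link" else "required-object"
    return(finding(path, rule, sev, sprintf("object '%s' unreachable", path)))
  }
  f <- rbind(f, verify_attributes(file, path, spec$attributes))
  f <- rbind(f, verify_relationship_presence(file, path, spec$relationships))
  kind <- spec_kind(spec)
  if (kind == "dataset") {
    f <- rbind(f, verify_dimensions(file, path, spec$dimensions))
    return(f)
  }
  # group children
  children <- h5_ls(file, path)
  kinds <- vapply(children, function(ch)
    h5_obj_kind(file, h5_path_join(path, ch)), character(1))
  reachable <- vapply(children, function(ch)
    h5_object_exists(file, h5_path_join(path, ch)), logical(1))
  for (ch in children[!reachable]) {
    f <- rbind(f, finding(h5_path_join(path, ch), "broken-link", "error",
                          sprintf("link '%s' does not resolve", ch)))
  }
  children <- children[reachable]
  kinds <- kinds[reachable]

  match_children <- function(node, want_kind) {
    nm <- spec_node_name(node); pf <- spec_node_prefix(node)
    hit <- if (!is.null(nm)) children == nm else startsWith(children, pf)
    children[hit & kinds == want_kind]
  }

  for (key in names(spec$datasets)) {
    node <- spec$datasets[[key]]
    hits <- match_children(node, "dataset")
    if (!length(hits)) {
      if (!isTRUE(node$optional))
        f <- rbind(f, finding(
          h5_path_join(path, spec_node_name(node) %||%
                         spec_node_prefix(node)),
          "required-dataset", "error",
          sprintf("required dataset '%s' missing",
                  spec_node_name(node) %||% spec_node_prefix(node))))
      next
    }
    for (ch in hits)
      f <- rbind(f, verify_node(file, h5_path_join(path, ch), node, registry))
  }
  for (key in names(spec$groups)) {
    node <- spec$groups[[key]]
    hits <- match_children(node, "group")
    if (!length(hits)) {
      if (!isTRUE(node$optional))
        f <- rbind(f, finding(
          h5_path_join(path, spec_node_name(node) %||%
                         spec_node_prefix(node)),
          "required-group", "error",
          sprintf("required group '%s' missing",
                  spec_node_name(node) %||% spec_node_prefix(node))))
      next
    }
    for (ch in hits)
      f <- rbind(f, verify_node(file, h5_path_join(path, ch), node, registry))
  }
  for (key in names(spec$managed)) {
    ref <- spec$managed[[key]]
    cand <- character()
    for (ch in children) {
      p <- h5_path_join(path, ch)
      if (!is_managed_path(file, p)) next
      t <- h5_read_attr(file, p, ATTR_MANAGED_TYPE)
      if (registry_is_subtype(registry, t, ref$managed_type)) {
        if (!is.null(ref$name) && ch != ref$name) next
        if (!is.null(ref$prefix) && !startsWith(ch, ref$prefix)) next
        cand <- c(cand, ch)
      }
    }
    if (!length(cand)) {
      if (!isTRUE(ref$optional))
        f <- rbind(f, finding(path, "required-managed", "error",
                              sprintf("no managed child of type '%s'",
                                      ref$managed_type)))
      next
    }
    for (ch in cand) {
      sub <- verify_compliance(new_handle(file, h5_path_join(path, ch),
                                          "group"),
                               registry = registry)
      f <- rbind(f, sub$findings)
    }
  }
  f
}

verify_attributes <- function(file, path, specs) {
  f <- no_findings()
  if (!length(specs)) return(f)
  present <- h5_ls_attrs(file, path)
  for (node in specs) {
    nm <- node$attribute
    hits <- if (!is.null(nm)) intersect(present, nm)
            else present[startsWith(present, node$prefix)]
    if (!length(hits)) {
      if (!isTRUE(node$optional))
        f <- rbind(f, finding(path, "required-attribute", "error",
                              sprintf("required attribute '%s' missing",
                                      nm %||% node$prefix)))
      next
    }
    if (!is.null(node$value)) {
      for (a in hits) {
        stored <- h5_read_attr(file, path, a)
        if (!identical(as.character(stored), as.character(node$value)))
          f <- rbind(f, finding(path, "fixed-value", "error",
                                sprintf("attribute '%s' is '%s', expected '%s'",
                                        a, paste(stored, collapse = ","),
                                        paste(node$value, collapse = ","))))
      }
    }
  }
  f
}

verify_dimensions <- function(file, path, specs) {
  f <- no_findings()
  if (!length(specs)) return(f)
  dims <- h5_dataset_dims(file, path)
  parent <- h5_parent_path(path)
  for (node in specs) {
    spath <- h5_path_join(parent, node$dataset)
    if (!h5_object_exists(file, spath)) {
      if (!isTRUE(node$optional))
        f <- rbind(f, finding(spath, "required-scale", "error",
                              sprintf("scale dataset '%s' missing",
                                      node$dataset)))
      next
    }
    if (node$axis >= length(dims)) {
      f <- rbind(f, finding(path, "scale-axis", "error",
                            sprintf("scale '%s' names axis %d of a rank-%d dataset",
                                    node$name, node$axis, length(dims))))
      next
    }
    if (!h5_ds_is_attached(file, spath, path, node$axis))
      f <- rbind(f, finding(spath, "scale-attachment", "error",
                            sprintf("scale '%s' not attached to axis %d",
                                    node$name, node$axis)))
    slen <- h5_dataset_dims(file, spath)[1]
    if (slen != dims[node$axis + 1])
      f <- rbind(f, finding(spath, "scale-length", "error",
                            sprintf("scale '%s' length %d != axis extent %d",
                                    node$name, slen, dims[node$axis + 1])))
  }
  f
}

verify_relationship_presence <- function(file, path, specs) {
  f <- no_findings()
  if (!length(specs)) return(f)
  present <- h5_ls_attrs(file, path)
  for (node in specs) {
    attr_name <- paste0(RELATIONSHIP_ATTR_PREFIX, node$attribute)
    hits <- present[startsWith(present, attr_name)]
    if (!length(hits) && !isTRUE(node$optional))
      f <- rbind(f, finding(path, "required-relationship", "error",
                            sprintf("required relationship '%s' missing",
                                    node$attribute)))
  }
  f
}

# ---- discovery --------------------------------------------------------------

#' Find managed objects in a container
#'
#' @param container Handle or file path.
#' @param type_name Optional type filter; matches the type itself and, by
#'   default, any derived type.
#' @param recursive Descend into subgroups (including through external
#'   links)?
#' @param exact Require an exact type match instead of subtype matching?
#' @param registry Managed type registry.
#' @return List of handles sorted by object path.
#' @export
find_managed_objects <- function(container, type_name = NULL,
                                 recursive = TRUE, exact = FALSE,
                                 registry = default_registry()) {
  h <- as_handle(container)
  found <- list()
  walk <- function(path) {
    children <- tryCatch(h5_ls(h$file, path), error = function(e) character())
    for (ch in children) {
      p <- h5_path_join(path, ch)
      if (!h5_object_exists(h$file, p)) next   # dangling link
      if (h5_obj_kind(h$file, p) != "group") next
      if (is_managed_path(h$file, p)) {
        t <- h5_read_attr(h$file, p, ATTR_MANAGED_TYPE)
        keep <- is.null(type_name) ||
          (if (exact) identical(t, type_name)
           else registry_is_subtype(registry, t, type_name))
        if (keep)
          found[[length(found) + 1L]] <<- wrap_managed_object(h$file, p,
                                                              registry)
      }
      if (recursive) walk(p)
    }
  }
  walk(h$path)
  found[order(vapply(found, function(x) x$path, character(1)))]
}

# ---- external / modular storage ---------------------------------------------

#' Create a managed object stored in an external file
#'
#' The object itself lives at the root of a generic managed container file
#' (`ManagedObjectContainer`) and is included in the parent via an HDF5
#' external link, so all discovery, verification, and mapping operations
#' behave exactly as for internal storage.
#'
#' @inheritParams create_managed_object
#' @param external_path Filesystem path of the external HDF5 file.
#' @return Handle of the new object, addressed through the parent file.
#' @export
create_external_managed_object <- function(parent, type_name, external_path,
                                           name, payload = list(),
                                           description = NULL,
                                           object_id = NULL,
                                           registry = default_registry()) {
  parent <- as_handle(parent)
  entry <- registry_entry(registry, type_name)
  obj_name <- resolve_object_name(entry$spec_factory(), name)
  link_path <- h5_path_join(parent$path, obj_name)
  if (h5_link_exists(parent$file, link_path))
    stop(sprintf("name collision: '%s' already exists", link_path))
  container <- create_managed_file(external_path, "ManagedObjectContainer",
                                   registry = registry)
  ok <- FALSE
  on.exit(if (!ok) unlink(external_path))
  create_managed_object(container, type_name, name = obj_name,
                        payload = payload, description = description,
                        object_id = object_id, registry = registry)
  # link relative to the parent file's directory for relocatable bundles
  rel <- external_path
  pdir <- normalizePath(dirname(parent$file))
  if (startsWith(normalizePath(external_path), paste0(pdir, "/")))
    rel <- substring(normalizePath(external_path), nchar(pdir) + 2L)
  h5_create_external_link(parent$file, link_path, rel,
                          h5_path_join("/", obj_name))
  ok <- TRUE
  wrap_managed_object(parent$file, link_path, registry)
}

# ---- multi-file containers ---------------------------------------------------

#' Group session files in a managed multi-file container
#'
#' Each member file is represented by a group `/entry_#` holding an
#' external link to the member's root, numbered densely in insertion
#' order, so a collection of related files can be traversed as if it were
#' one file.
#'
#' @param path Filesystem path of the container file.
#' @param overwrite Replace an existing file?
#' @param registry Managed type registry.
#' @return Handle of the container root (type `BrainDataMultiFile`).
#' @export
create_multifile_container <- function(path, overwrite = FALSE,
                                       registry = default_registry()) {
  create_managed_file(path, "BrainDataMultiFile", overwrite = overwrite,
                      registry = registry)
}

#' @rdname create_multifile_container
#' @param container Handle (or path) of a multi-file container.
#' @param member_file Filesystem path of a managed HDF5 file to add.
#' @return `add_container_entry()`: the new entry name, e.g. `"entry_0"`.
#' @export
add_container_entry <- function(container, member_file,
                                registry = default_registry()) {
  h <- as_handle(container)
  if (!identical(h$managed_type, "BrainDataMultiFile"))
    stop("container is not a BrainDataMultiFile")
  if (!h5_is_hdf5(member_file) || !is_managed_path(member_file, "/"))
    stop("member is not a managed HDF5 file: ", member_file)
  entries <- grep("^entry_[0-9]+$", h5_ls(h$file, "/"), value = TRUE)
  entry <- paste0("entry_", length(entries))
  h5_create_external_link(h$file, h5_path_join("/", entry), member_file, "/")
  entry
}
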