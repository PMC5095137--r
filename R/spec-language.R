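#' Format-specification language
#'
#' A format specification is a hierarchical, JSON-serializable document
#' describing an HDF5 file, group, or dataset together with its attributes,
#' dimension scales, managed children, and relationship attributes.
#' Specifications are *minimal*: everything they name must be present and
#' conforming, but files may always contain additional, unspecified objects
#' without losing compliance.
#'
#' Every node carries a `kind` discriminator so that documents round-trip
#' through JSON without loss. Child objects are addressed by an exact `name`
#' or by a `prefix` (matched as "starts with"); exactly one of the two must
#' be given. All axis numbers are 0-based.
#'
#' @name spec-language
NULL

SPEC_KINDS <- c("attribute", "dimension", "dataset", "group", "managed",
                "relationship", "format_document")

RELATIONSHIP_TYPES <- c("order", "equivalent", "indexes", "shared_encoding",
                        "shared_ascending_encoding", "indexes_values", "user")

new_spec_node <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("neurofmt_", kind, "_spec"), "neurofmt_spec"))
}

#' Specify an HDF5 attribute
#'
#' @param attribute Exact attribute name, or `NULL` when `prefix` is used.
#' @param prefix Name prefix matching any attribute that starts with it.
#' @param value Optional fixed literal; verification requires the stored
#'   attribute to equal it exactly.
#' @param optional Is the attribute optional?
#' @param description Human-readable description.
#' @return An attribute spec node.
#' @export
attribute_spec <- function(attribute = NULL, prefix = NULL, value = NULL,
                           optional = FALSE, description = "") {
  new_spec_node("attribute", list(
    attribute = attribute, prefix = prefix, value = value,
    optional = isTRUE(optional), description = description))
}

#' Specify a dimension scale of a dataset
#'
#' @param name Scale name (e.g. `"space"`, `"time"`).
#' @param unit Unit string of the scale values.
#' @param dataset Name of the scale dataset within the parent group.
#' @param axis 0-based axis of the described dataset.
#' @param optional Is the scale optional?
#' @param description Human-readable description.
#' @return A dimension spec node.
#' @export
dimension_spec <- function(name, unit, dataset, axis, optional = FALSE,
                           description = "") {
  stopifnot(is.numeric(axis))
  new_spec_node("dimension", list(
    name = name, unit = unit, dataset = dataset, axis = as.integer(axis),
    optional = isTRUE(optional), description = description))
}

#' Specify a dataset
#'
#' @param dataset Exact dataset name, or `NULL` when `prefix` is used.
#' @param prefix Name prefix.
#' @param optional Is the dataset optional?
#' @param primary Flag marking a primary dataset for visualization and
#'   analysis.
#' @param description Human-readable description.
#' @return A dataset spec node with empty `attributes`, `dimensions`, and
#'   `relationships` collections; populate them with [attach_child_spec()].
#' @export
dataset_spec <- function(dataset = NULL, prefix = NULL, optional = FALSE,
                         primary = FALSE, description = "") {
  new_spec_node("dataset", list(
    dataset = dataset, prefix = prefix, optional = isTRUE(optional),
    primary = isTRUE(primary), description = description,
    attributes = list(), dimensions = list(), relationships = list()))
}

#' Specify a group (or a file, as a group rooted at "/")
#'
#' @param group Exact group name, or `NULL` when `prefix` is used. The root
#'   of a file spec uses `group = "/"`.
#' @param prefix Name prefix.
#' @param optional Is the group optional?
#' @param description Human-readable description.
#' @return A group spec node with empty child collections.
#' @export
group_spec <- function(group = NULL, prefix = NULL, optional = FALSE,
                       description = "") {
  new_spec_node("group", list(
    group = group, prefix = prefix, optional = isTRUE(optional),
    description = description,
    attributes = list(), datasets = list(), groups = list(),
    managed = list(), relationships = list()))
}

#' @rdname group_spec
#' @export
file_spec <- function(description = "") {
  group_spec(group = "/", description = description)
}

#' Reference a managed object type inside a group spec
#'
#' @param managed_type Registered managed type name.
#' @param optional Is the child optional?
#' @param name,prefix Optional override of the referenced type's own
#'   name/prefix rule.
#' @param description Human-readable description.
#' @return A managed-reference spec node.
#' @export
managed_ref <- function(managed_type, optional = FALSE, name = NULL,
                        prefix = NULL, description = "") {
  new_spec_node("managed", list(
    managed_type = managed_type, optional = isTRUE(optional),
    name = name, prefix = prefix, description = description))
}

#' Specify a relationship attribute
#'
#' Relationship attributes declare a typed semantic link from the object
#' carrying the attribute (the source) to a target object, and imply rules
#' for mapping element selections from source to target (see
#' [map_selection()]).
#'
#' @param attribute User-visible relationship name (stored on disk under the
#'   reserved `RELATIONSHIP_ATTR_` prefix).
#' @param relationship_type One of `order`, `equivalent`, `indexes`,
#'   `shared_encoding`, `shared_ascending_encoding`, `indexes_values`,
#'   `user`.
#' @param target_location Absolute HDF5 path of the target, or a
#'   `list(file=, path=)` for a target in another file.
#' @param source_axes,target_axes `NULL` (whole object), a single 0-based
#'   axis, a vector of axes, or a named list mapping axis names to indices.
#'   When both are vectors/maps they must have equal length / key sets.
#' @param optional Is the relationship optional?
#' @param description Human-readable description.
#' @param properties Free-form named list of user metadata.
#' @return A relationship spec node.
#' @export
relationship_spec <- function(attribute, relationship_type, target_location,
                              source_axes = NULL, target_axes = NULL,
                              optional = FALSE, description = "",
                              properties = NULL) {
  new_spec_node("relationship", list(
    attribute = attribute, optional = isTRUE(optional),
    description = description, properties = properties,
    relationship_type = relationship_type,
    source_axes = normalize_axes(source_axes),
    target = list(location = target_location,
                  axes = normalize_axes(target_axes))))
}

normalize_axes <- function(axes) {
  if (is.null(axes)) return(NULL)
  if (is.list(axes) || !is.null(names(axes))) {
    lapply(as.list(axes), function(a) as.integer(a))
  } else {
    as.integer(axes)
  }
}

spec_kind <- function(doc) {
  if (!is.list(doc) || is.null(doc$kind)) NULL else doc$kind
}

spec_node_name <- function(doc) {
  switch(spec_kind(doc),
         attribute = doc$attribute, dataset = doc$dataset,
         group = doc$group, managed = doc$name,
         dimension = doc$name, relationship = doc$attribute,
         NULL)
}

spec_node_prefix <- function(doc) {
  if (spec_kind(doc) %in% c("attribute", "dataset", "group", "managed"))
    doc$prefix else NULL
}

#' @export
print.neurofmt_spec <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  cat(spec_to_json(x, pretty = TRUE), "\n")
  invisible(x)
}

# ---- validation ------------------------------------------------------------

report_entry <- function(path, severity, message) {
  data.frame(path = path, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(path = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a specification document against the meta-schema
#'
#' Checks field presence, enum membership, the name-XOR-prefix rule, axis
#' bounds, duplicate child detection, and the shape agreement between
#' relationship source and target axes, recursively.
#'
#' @param doc A spec node built with the constructors of this package or
#'   parsed with [spec_from_json()].
#' @return A data frame with columns `path`, `severity`, `message`; zero
#'   rows means the document is meta-valid.
#' @export
validate_spec_document <- function(doc) {
  if (!is.list(doc) || is.null(spec_kind(doc)) ||
      !(spec_kind(doc) %in% SPEC_KINDS)) {
    stop("not a specification document (missing or unknown 'kind')")
  }
  validate_node(doc, "/")
}

validate_node <- function(doc, path) {
  rep <- empty_report()
  kind <- spec_kind(doc)
  if (is.null(kind) || !(kind %in% SPEC_KINDS)) {
    return(report_entry(path, "error",
                        "node has missing or unknown 'kind'"))
  }
  add <- function(msg) report_entry(path, "error", msg)

  if (kind == "format_document") {
    for (nm in names(doc$types))
      rep <- rbind(rep, validate_node(doc$types[[nm]],
                                      h5_path_join(path, nm)))
    return(rep)
  }

  if (kind %in% c("attribute", "dataset", "group", "managed")) {
    nm <- spec_node_name(doc)
    pf <- spec_node_prefix(doc)
    if (kind == "managed") {
      if (is.null(doc$managed_type) || !nzchar(doc$managed_type))
        rep <- rbind(rep, add("managed reference requires a managed_type"))
      # name/prefix are optional overrides on managed refs, both may be NULL
      if (!is.null(nm) && !is.null(pf))
        rep <- rbind(rep, add("give a name or a prefix override, not both"))
    } else if (is.null(nm) == is.null(pf)) {
      rep <- rbind(rep, add(sprintf(
        "exactly one of {%s, prefix} must be non-null",
        if (kind == "attribute") "attribute" else kind)))
    }
  }

  if (kind == "attribute" && !is.null(doc$value) && length(doc$value) == 0)
    rep <- rbind(rep, add("fixed 'value' must be a non-empty literal"))

  if (kind == "dimension") {
    for (fld in c("name", "unit", "dataset"))
      if (is.null(doc[[fld]]) || !nzchar(as.character(doc[[fld]])[1]))
        rep <- rbind(rep, add(paste0("dimension requires field '", fld, "'")))
    if (is.null(doc$axis) || doc$axis < 0)
      rep <- rbind(rep, add("dimension axis must be >= 0"))
  }

  if (kind == "relationship") {
    if (is.null(doc$attribute) || !nzchar(doc$attribute))
      rep <- rbind(rep, add("relationship requires an attribute name"))
    if (is.null(doc$relationship_type) ||
        !(doc$relationship_type %in% RELATIONSHIP_TYPES))
      rep <- rbind(rep, add(sprintf(
        "relationship_type must be one of {%s}",
        paste(RELATIONSHIP_TYPES, collapse = ", "))))
    if (is.null(doc$target) || is.null(doc$target$location))
      rep <- rbind(rep, add("relationship requires target$location"))
    sa <- doc$source_axes; ta <- doc$target$axes
    if (!is.null(sa) && !is.null(ta)) {
      if (is.list(sa) != is.list(ta)) {
        rep <- rbind(rep, add("source and target axes must share their shape"))
      } else if (is.list(sa)) {
        if (!setequal(names(sa), names(ta)))
          rep <- rbind(rep, add("source/target axis maps must share key sets"))
      } else if (length(sa) != length(ta)) {
        rep <- rbind(rep, add("source/target axis lists must share length"))
      }
    }
  }

  # recurse into child collections, checking duplicate identities
  for (coll in c("attributes", "dimensions", "datasets", "groups",
                 "managed", "relationships")) {
    if (kind == "managed") break
    children <- doc[[coll]]
    if (is.null(children) || length(children) == 0) next
    if (!is.list(children)) {
      rep <- rbind(rep, add(paste0("collection '", coll, "' must be a list")))
      next
    }
    keys <- names(children)
    if (is.null(keys) || any(!nzchar(keys)) || anyDuplicated(keys)) {
      rep <- rbind(rep, add(paste0(
        "collection '", coll, "' must have unique non-empty keys")))
    }
    if (coll == "dimensions") {
      ids <- vapply(children, function(d)
        paste0(d$axis, ":", d$name), character(1))
      if (anyDuplicated(ids))
        rep <- rbind(rep, add("duplicate (axis, name) among dimensions"))
    }
    if (coll == "attributes") {
      nms <- unlist(lapply(children, function(a) a$attribute))
      if (anyDuplicated(nms[!is.na(nms)]))
        rep <- rbind(rep, add("duplicate exact attribute names"))
    }
    for (key in keys)
      rep <- rbind(rep, validate_node(children[[key]],
                                      h5_path_join(path, coll, key)))
  }
  rep
}

# ---- incremental construction ----------------------------------------------

CHILD_COLLECTION <- c(attribute = "attributes", dimension = "dimensions",
                      dataset = "datasets", group = "groups",
                      managed = "managed", relationship = "relationships")

#' Attach a child spec to a parent spec
#'
#' Attributes and relationships may be attached to groups and datasets;
#' dimensions only to datasets; datasets, groups, and managed references
#' only to groups. Attaching under an existing key is a collision error.
#'
#' @param parent A group or dataset spec.
#' @param child The child spec node.
#' @param key Key within the parent's collection; defaults to the child's
#'   name or prefix.
#' @return The updated parent.
#' @export
attach_child_spec <- function(parent, child, key = NULL) {
  pk <- spec_kind(parent); ck <- spec_kind(child)
  if (!(pk %in% c("group", "dataset")))
    stop("parent must be a group or dataset spec")
  if (is.null(ck) || !(ck %in% names(CHILD_COLLECTION)))
    stop("child is not an attachable spec node")
  legal <- if (pk == "group") {
    c("attribute", "dataset", "group", "managed", "relationship")
  } else {
    c("attribute", "dimension", "relationship")
  }
  if (!(ck %in% legal))
    stop(sprintf("cannot attach a %s spec to a %s spec", ck, pk))
  if (is.null(key)) {
    key <- spec_node_name(child)
    if (is.null(key)) key <- spec_node_prefix(child)
    if (is.null(key) && ck == "managed") key <- child$managed_type
  }
  if (is.null(key) || !nzchar(key))
    stop("no key given and child has neither name nor prefix")
  coll <- CHILD_COLLECTION[[ck]]
  if (key %in% names(parent[[coll]]))
    stop(sprintf("collision: key '%s' already present in %s", key, coll))
  parent[[coll]][[key]] <- child
  parent
}

#' @rdname attach_child_spec
#' @export
add_attribute <- function(parent, child, key = NULL) {
  attach_child_spec(parent, child, key)
}

#' @rdname attach_child_spec
#' @export
add_dimension <- function(parent, child, key = NULL) {
  attach_child_spec(parent, child, key)
}

#' @rdname attach_child_spec
#' @export
add_dataset <- function(parent, child, key = NULL) {
  attach_child_spec(parent, child, key)
}

# ---- JSON serialization ----------------------------------------------------

#' Serialize / parse specification documents as JSON
#'
#' `spec_to_json()` writes UTF-8 JSON with stable key ordering;
#' `spec_from_json()` is its inverse: `spec_from_json(spec_to_json(doc))`
#' is structurally identical to `doc` for any meta-valid document.
#'
#' @param doc A spec node.
#' @param pretty Pretty-print with indentation?
#' @param text JSON text.
#' @return `spec_to_json()` a character scalar; `spec_from_json()` a spec
#'   node.
#' @export
spec_to_json <- function(doc, pretty = FALSE) {
  as.character(toJSON(spec_strip(doc), pretty = pretty, auto_unbox = TRUE,
                      null = "null", digits = NA))
}

# drop class attributes recursively for serialization
spec_strip <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, spec_strip)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(text) {
  doc <- tryCatch(
    fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("cannot parse JSON spec: ", conditionMessage(e)))
  spec_rehydrate(doc)
}

spec_rehydrate <- function(x) {
  if (!is.list(x)) return(x)
  kind <- x$kind
  x <- lapply(x, spec_rehydrate)
  # scalar-list fields parsed by fromJSON stay lists only where intended
  if (!is.null(kind) && kind %in% SPEC_KINDS) {
    for (fld in c("optional", "primary")) {
      if (!is.null(x[[fld]])) x[[fld]] <- isTRUE(x[[fld]])
    }
    if (!is.null(x$axis)) x$axis <- as.integer(x$axis)
    if (!is.null(x$source_axes)) x$source_axes <- rehydrate_axes(x$source_axes)
    if (!is.null(x$target) && !is.null(x$target$axes))
      x$target$axes <- rehydrate_axes(x$target$axes)
    return(new_spec_node(kind, x[setdiff(names(x), "kind")]))
  }
  x
}

rehydrate_axes <- function(a) {
  if (is.list(a) && is.null(names(a))) {
    as.integer(unlist(a))
  } else if (is.list(a)) {
    lapply(a, as.integer)
  } else {
    as.integer(a)
  }
}

# structural equality ignoring attribute ordering; used by tests and
# documented as the round-trip contract
spec_identical <- function(a, b) {
  identical(spec_strip(a), spec_strip(b))
}

# ---- recursive compilation --------------------------------------------------

#' Recursively compile the full specification of a managed type
#'
#' Replaces every managed reference in the type's basic spec by the
#' referenced type's own (recursively compiled) spec, annotated with its
#' origin type name under `managed_type`. Cyclic references are an error.
#'
#' @param type_name Registered managed type name.
#' @param registry A managed type registry (defaults to the package
#'   registry).
#' @return A meta-valid group/dataset spec with no unresolved managed
#'   references.
#' @export
compile_recursive_spec <- function(type_name, registry = default_registry()) {
  compile_rec(type_name, registry, stack = character())
}

compile_rec <- function(type_name, registry, stack) {
  if (type_name %in% stack) {
    cycle <- c(stack[seq(match(type_name, stack), length(stack))], type_name)
    stop("cyclic managed reference: ", paste(cycle, collapse = " -> "))
  }
  spec <- registry_spec(registry, type_name)
  inline_refs(spec, registry, c(stack, type_name), at = type_name)
}

inline_refs <- function(node, registry, stack, at) {
  if (length(node$managed)) {
    for (key in names(node$managed)) {
      ref <- node$managed[[key]]
      if (!registry_has(registry, ref$managed_type))
        stop(sprintf("unknown managed type '%s' referenced at %s/%s",
                     ref$managed_type, at, key))
      sub <- compile_rec(ref$managed_type, registry, stack)
      sub$managed_type <- ref$managed_type
      if (!is.null(ref$name)) { sub$group <- ref$name; sub$prefix <- NULL }
      if (!is.null(ref$prefix)) { sub$prefix <- ref$prefix; sub$group <- NULL }
      sub$optional <- isTRUE(ref$optional)
      node$groups[[key]] <- sub
    }
    node$managed <- list()
  }
  if (length(node$groups)) {
    for (key in names(node$groups))
      node$groups[[key]] <- inline_refs(node$groups[[key]], registry, stack,
                                        paste0(at, "/", key))
  }
  node
}

#' Compile a format document covering every registered type
#'
#' The document maps each registered managed type name to its *basic*
#' (non-recursive) specification, together with a format name and version.
#' Unlike [compile_recursive_spec()] this never inlines references, so it
#' tolerates cyclic type graphs.
#'
#' @param registry A managed type registry.
#' @param format_name Name recorded in the document.
#' @param version Semantic version string recorded in the document.
#' @return A `format_document` spec node.
#' @export
compile_format_document <- function(registry = default_registry(),
                                    format_name = "neurofmt",
                                    version = SPEC_VERSION) {
  types <- list()
  for (nm in sort(registry_types(registry)))
    types[[nm]] <- registry_spec(registry, nm)
  new_spec_node("format_document", list(
    format = format_name, version = version, types = types))
}

SPEC_VERSION <- "1.0.0"

`%||%` <- function(a, b) if (is.null(a)) b else a
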