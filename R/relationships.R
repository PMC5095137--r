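#' Relationship attributes
#'
#' A relationship attribute is a JSON-valued HDF5 attribute stored on a
#' source object, declaring a typed semantic link to a target object. The
#' attribute name carries the reserved prefix `RELATIONSHIP_ATTR_`; the
#' value is a self-contained JSON document (the relationship descriptor).
#' Every relationship type except `user` implies a rule for mapping
#' element selections from source to target; see [map_selection()].
#'
#' @name relationships
NULL

RELATIONSHIP_ATTR_PREFIX <- "RELATIONSHIP_ATTR_"

IMR_POSTFIXES <- c(SOURCE_TO_MAP = "_IMR_SOURCE_TO_MAP",
                   MAP_TO_SOURCE = "_IMR_MAP_TO_SOURCE",
                   MAP_TO_TARGET = "_IMR_MAP_TO_TARGET",
                   SOURCE_TO_TARGET = "_IMR_SOURCE_TO_TARGET")

new_relationship <- function(file, source_path, name, spec) {
  structure(list(file = file, source_path = source_path, name = name,
                 attr_name = paste0(RELATIONSHIP_ATTR_PREFIX, name),
                 spec = spec),
            class = "neurofmt_relationship")
}

#' @export
print.neurofmt_relationship <- function(x, ...) {
  tgt <- x$spec$target$location
  if (is.list(tgt)) tgt <- paste0(tgt$file, ":", tgt$path)
  cat(sprintf("<relationship '%s'> %s --%s--> %s\n", x$name,
              x$source_path, x$spec$relationship_type, tgt))
  invisible(x)
}

resolve_target <- function(rel) {
  loc <- rel$spec$target$location
  if (is.list(loc)) {
    list(file = file.path(dirname(rel$file), loc$file), path = loc$path)
  } else {
    # non-absolute locations are relative to the source's parent group
    if (!startsWith(loc, "/"))
      loc <- h5_path_join(h5_parent_path(rel$source_path), loc)
    list(file = rel$file, path = loc)
  }
}

#' Create a relationship attribute on a source object
#'
#' @param source Handle (or file path) of the source object.
#' @param name User-visible relationship name; stored under
#'   `RELATIONSHIP_ATTR_<name>`.
#' @param relationship_type One of the seven relationship types; see
#'   [relationship_spec()].
#' @param target Target location: a handle, an absolute HDF5 path in the
#'   same file, or `list(file=, path=)`.
#' @param source_axes,target_axes Axes the relationship applies to
#'   (`NULL` = whole object).
#' @param description,properties Human-readable description and free
#'   key-value metadata.
#' @param allow_dangling Permit a target that does not (yet) resolve;
#'   verification then reports a warning finding instead of failing
#'   creation.
#' @return A relationship handle.
#' @export
create_relationship_attribute <- function(source, name, relationship_type,
                                          target, source_axes = NULL,
                                          target_axes = NULL,
                                          description = "",
                                          properties = NULL,
                                          allow_dangling = FALSE) {
  source <- as_handle(source)
  if (inherits(target, "neurofmt_handle")) {
    target <- if (identical(target$file, source$file)) target$path
              else list(file = target$file, path = target$path)
  }
  spec <- relationship_spec(attribute = name,
                            relationship_type = relationship_type,
                            target_location = target,
                            source_axes = source_axes,
                            target_axes = target_axes,
                            description = description,
                            properties = properties)
  rep <- validate_spec_document(spec)
  if (nrow(rep) > 0)
    stop("invalid relationship descriptor: ",
         paste(rep$message, collapse = "; "))
  attr_name <- paste0(RELATIONSHIP_ATTR_PREFIX, name)
  if (h5_attr_exists(source$file, source$path, attr_name))
    stop(sprintf("relationship '%s' already exists on %s", name,
                 source$path))
  rel <- new_relationship(source$file, source$path, name, spec)
  tgt <- resolve_target(rel)
  if (!file.exists(tgt$file) || !h5_object_exists(tgt$file, tgt$path)) {
    if (!allow_dangling)
      stop(sprintf("relationship target '%s' does not resolve",
                   if (is.list(target)) target$path else target))
  }
  h5_write_attr(source$file, source$path, attr_name, spec_to_json(spec))
  rel
}

read_relationship <- function(file, path, attr_name) {
  spec <- spec_from_json(h5_read_attr(file, path, attr_name))
  name <- substring(attr_name, nchar(RELATIONSHIP_ATTR_PREFIX) + 1L)
  new_relationship(file, path, name, spec)
}

#' List and search relationship attributes
#'
#' `list_relationship_attributes()` returns every relationship stored on
#' an object (attributes carrying the reserved prefix), in name order.
#' `find_relationships()` filters a source object's relationships by
#' resolved target.
#'
#' @param x Handle (or file path) of the object.
#' @return List of relationship handles.
#' @export
list_relationship_attributes <- function(x) {
  h <- as_handle(x)
  attrs <- h5_ls_attrs(h$file, h$path)
  attrs <- attrs[startsWith(attrs, RELATIONSHIP_ATTR_PREFIX)]
  lapply(attrs, function(a) read_relationship(h$file, h$path, a))
}

#' @rdname list_relationship_attributes
#' @param source Source handle.
#' @param target Target handle or absolute HDF5 path.
#' @export
find_relationships <- function(source, target) {
  source <- as_handle(source)
  if (inherits(target, "neurofmt_handle")) {
    tfile <- target$file; tpath <- target$path
  } else {
    tfile <- source$file; tpath <- target
  }
  rels <- list_relationship_attributes(source)
  Filter(function(r) {
    tgt <- resolve_target(r)
    identical(normalizePath(tgt$file, mustWork = FALSE),
              normalizePath(tfile, mustWork = FALSE)) &&
      identical(tgt$path, tpath)
  }, rels)
}

#' @rdname list_relationship_attributes
#' @param name Relationship name (without the reserved prefix).
#' @export
get_relationship <- function(x, name) {
  h <- as_handle(x)
  read_relationship(h$file, h$path, paste0(RELATIONSHIP_ATTR_PREFIX, name))
}

# ---- selection mapping -------------------------------------------------------

# axes of the source the relationship applies to (0-based vector), given
# the source rank
related_axes <- function(spec, rank) {
  sa <- spec$source_axes
  if (is.null(sa)) return(seq_len(rank) - 1L)
  as.integer(unlist(sa))
}

#' Map a selection from the source to the target of a relationship
#'
#' Implements the per-type mapping rules:
#' \describe{
#'   \item{order / equivalent}{identity on element indices along the
#'     related axes (group members are taken in alphabetic order).}
#'   \item{indexes}{the source stores indices into the target; the mapped
#'     selection is the gathered index values at the selected positions.
#'     Multi-axis index maps carry an index axis (one slot per target
#'     axis) and optionally a stacking axis for N-to-M mappings, with
#'     unused stacking slots filled by the sentinel -1 (dropped).}
#'   \item{shared_encoding / indexes_values}{value matching: all target
#'     positions whose value equals any selected source value.}
#'   \item{shared_ascending_encoding}{range selections map to all target
#'     positions with value in `[min, max]` of the selected source
#'     values; point selections fall back to exact value matching.}
#'   \item{user}{no implied mapping; always an error.}
#' }
#' Mapped selections are deduplicated and ascending; a contiguous 1-D
#' result is expressed as a half-open range.
#'
#' @param rel Relationship handle.
#' @param sel A [selection()].
#' @return A selection on the target (a point-set selection when the
#'   target has rank > 1).
#' @export
map_selection <- function(rel, sel) {
  stopifnot(inherits(rel, "neurofmt_relationship"))
  type <- rel$spec$relationship_type
  if (type == "user")
    stop("user relationships define no implied mapping between elements")
  tgt <- resolve_target(rel)
  src_kind <- h5_obj_kind(rel$file, rel$source_path)
  if (src_kind == "group")
    return(map_selection_group(rel, sel, tgt, type))

  sdims <- h5_dataset_dims(rel$file, rel$source_path)
  tdims <- h5_dataset_dims(tgt$file, tgt$path)

  if (type %in% c("order", "equivalent")) {
    axes <- related_axes(rel$spec, length(sdims))
    taxes <- rel$spec$target$axes
    taxes <- if (is.null(taxes)) axes else as.integer(unlist(taxes))
    # identity on indices; bounds-check against both extents
    idx <- selection_indices(sel, sdims[axes + 1])
    if (is.matrix(idx)) {
      for (k in seq_along(taxes))
        if (any(idx[, k] >= tdims[taxes[k] + 1]))
          stop("selection out of bounds on target")
      return(canonical_result(idx))
    }
    if (length(idx) && max(idx) >= tdims[taxes[1] + 1])
      stop("selection out of bounds on target")
    return(canonical_index_selection(idx))
  }

  if (type == "indexes") {
    return(map_indexes(rel, sel, sdims, tdims))
  }

  # value-based types: 1-D source/target semantics
  svals <- h5_read_dataset(rel$file, rel$source_path)
  tvals <- h5_read_dataset(tgt$file, tgt$path)
  idx <- selection_indices(sel, length(svals))
  picked <- svals[idx + 1]
  if (type %in% c("shared_encoding", "indexes_values")) {
    hits <- which(tvals %in% picked) - 1
    return(canonical_index_selection(hits))
  }
  if (type == "shared_ascending_encoding") {
    ranged <- length(sel$selectors) == 1 && is_range_selector(sel$selectors[[1]])
    if (ranged && length(picked)) {
      hits <- which(tvals >= min(picked) & tvals <= max(picked)) - 1
    } else {
      hits <- which(tvals %in% picked) - 1
    }
    return(canonical_index_selection(hits))
  }
  stop("unhandled relationship type: ", type)
}

# indexes semantics, including the rectangular index-map layout
# (spatial axes ..., index axis of length = target rank, stacking axis)
map_indexes <- function(rel, sel, sdims, tdims) {
  spatial <- related_axes(rel$spec, length(sdims))
  extra <- length(sdims) - length(spatial)
  m <- h5_read_dataset(rel$file, rel$source_path)
  if (extra == 0) {
    idx <- selection_indices(sel, sdims)
    vals <- if (is.matrix(idx)) m[idx + 1] else m[idx + 1]
    vals <- vals[vals >= 0]
    if (length(vals) && max(vals) >= prod(tdims))
      stop("index map points outside the target")
    return(canonical_index_selection(vals))
  }
  cells <- selection_indices(sel, sdims[spatial + 1])
  if (!is.matrix(cells)) cells <- matrix(cells, ncol = 1)
  trank <- length(tdims)
  has_index_axis <- extra == 2 || (extra == 1 && trank > 1)
  tuples <- NULL
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    slab <- extract_cell(m, sdims, spatial, cell)
    # slab dims: (index axis?, stacking axis?) in source axis order
    if (has_index_axis) {
      tup <- matrix(slab, nrow = trank)          # index axis varies fastest
      tup <- t(tup)
    } else {
      tup <- matrix(slab, ncol = 1)
    }
    keep <- apply(tup, 1, function(v) all(v >= 0))
    tuples <- rbind(tuples, tup[keep, , drop = FALSE])
  }
  if (is.null(tuples)) tuples <- matrix(numeric(), ncol = max(trank, 1))
  for (k in seq_len(ncol(tuples)))
    if (nrow(tuples) && any(tuples[, k] >= tdims[k]))
      stop("index map points outside the target")
  canonical_result(tuples)
}

# read one spatial cell of an index map: fixes the spatial axes at `cell`
# (0-based) and returns the remaining axes as a vector in axis order
extract_cell <- function(m, dims, spatial, cell) {
  args <- vector("list", length(dims))
  for (k in seq_along(dims)) args[[k]] <- seq_len(dims[k])
  for (j in seq_along(spatial)) args[[spatial[j] + 1]] <- cell[j] + 1
  do.call(`[`, c(list(m), args))
}

map_selection_group <- function(rel, sel, tgt, type) {
  smembers <- h5_ls(rel$file, rel$source_path)      # alphabetic order
  tmembers <- h5_ls(tgt$file, tgt$path)
  sl <- sel$selectors[[1]]
  ord <- if (sl$kind == "members") {
    missing <- setdiff(sl$members, smembers)
    if (length(missing))
      stop("unknown group member(s): ", paste(missing, collapse = ", "))
    match(sl$members, smembers) - 1
  } else {
    selector_indices(sl, length(smembers))
  }
  if (type %in% c("order", "equivalent")) {
    if (length(ord) && max(ord) >= length(tmembers))
      stop("selection out of bounds on target group")
    return(selection(sel_members(tmembers[sort(unique(ord)) + 1])))
  }
  if (type %in% c("shared_encoding", "indexes_values")) {
    hits <- sort(intersect(smembers[ord + 1], tmembers))
    return(selection(sel_members(hits)))
  }
  stop(sprintf("relationship type '%s' is not defined for group sources",
               type))
}

#' Read target values through a relationship
#'
#' Composes [map_selection()] with a read of the target: equivalent to
#' reading the target dataset with the mapped selection.
#'
#' @inheritParams map_selection
#' @return Array of target values (for datasets) or member names (for
#'   groups).
#' @export
select_through <- function(rel, sel) {
  mapped <- map_selection(rel, sel)
  tgt <- resolve_target(rel)
  if (h5_obj_kind(tgt$file, tgt$path) == "group")
    return(mapped$selectors[[1]]$members)
  vals <- h5_read_dataset(tgt$file, tgt$path)
  idx <- selection_indices(mapped, h5_dataset_dims(tgt$file, tgt$path))
  if (is.matrix(idx)) {
    if (nrow(idx) == 0) return(vals[0])
    apply(idx, 1, function(tuple)
      do.call(`[`, c(list(vals), as.list(tuple + 1))))
  } else {
    vals[idx + 1]
  }
}

# ---- index map relationships -------------------------------------------------

new_imr <- function(file, base_name, source, map, target, legs) {
  structure(list(file = file, base_name = base_name, source = source,
                 map = map, target = target, legs = legs),
            class = "neurofmt_imr")
}

#' @export
print.neurofmt_imr <- function(x, ...) {
  cat(sprintf("<index map relationship '%s'> %s -> %s -> %s (legs: %s)\n",
              x$base_name, x$source, x$map, x$target,
              paste(names(x$legs), collapse = ", ")))
  invisible(x)
}

#' Create an index map relationship
#'
#' Routes selections from a source array A through an explicit index map M
#' into a target B by creating a chain of relationship attributes under a
#' shared base name with reserved postfixes: an `order` leg A to M
#' (`_IMR_SOURCE_TO_MAP`), its inverse `order` leg M to A
#' (`_IMR_MAP_TO_SOURCE`), an `indexes` leg M to B (`_IMR_MAP_TO_TARGET`;
#' M stores indices into B), and — only when `user_properties` is given —
#' a `user` leg A to B (`_IMR_SOURCE_TO_TARGET`). Any leg failure rolls
#' back all created legs.
#'
#' @param source,index_map,target Handles (or absolute paths in
#'   `source$file`) of A, M, and B.
#' @param base_name Shared base name of the chain's attributes.
#' @param user_properties Named list; when non-`NULL` the optional user
#'   leg is created with these properties.
#' @param source_axes 0-based spatial axes of A (and M) the chain applies
#'   to; defaults to all axes of A.
#' @return An index map relationship bundle.
#' @export
create_index_map_relationship <- function(source, index_map, target,
                                          base_name,
                                          user_properties = NULL,
                                          source_axes = NULL) {
  source <- as_handle(source)
  imap <- if (inherits(index_map, "neurofmt_handle")) index_map
          else wrap_managed_object(source$file, index_map)
  tgt <- if (inherits(target, "neurofmt_handle")) target
         else wrap_managed_object(source$file, target)
  sdims <- h5_dataset_dims(source$file, source$path)
  if (is.null(source_axes)) source_axes <- seq_along(sdims) - 1
  created <- list()
  ok <- FALSE
  on.exit(if (!ok) for (cr in created)
    try(h5_delete_attr(cr$file, cr$source_path, cr$attr_name),
        silent = TRUE))
  mk <- function(src, nm, type, target, props = NULL) {
    r <- create_relationship_attribute(
      src, nm, type, target, source_axes = source_axes,
      target_axes = source_axes,
      description = sprintf("index map relationship leg '%s'", nm),
      properties = props)
    created[[length(created) + 1L]] <<- r
    r
  }
  legs <- list(
    SOURCE_TO_MAP = mk(source,
                       paste0(base_name, IMR_POSTFIXES[["SOURCE_TO_MAP"]]),
                       "order", imap),
    MAP_TO_SOURCE = mk(imap,
                       paste0(base_name, IMR_POSTFIXES[["MAP_TO_SOURCE"]]),
                       "order", source),
    MAP_TO_TARGET = create_relationship_attribute(
      imap, paste0(base_name, IMR_POSTFIXES[["MAP_TO_TARGET"]]),
      "indexes", tgt, source_axes = source_axes,
      description = "index map relationship leg 'MAP_TO_TARGET'"))
  created[[length(created) + 1L]] <- legs$MAP_TO_TARGET
  if (!is.null(user_properties)) {
    legs$SOURCE_TO_TARGET <- mk(
      source, paste0(base_name, IMR_POSTFIXES[["SOURCE_TO_TARGET"]]),
      "user", tgt, props = user_properties)
  }
  ok <- TRUE
  new_imr(source$file, base_name, source$path, imap$path, tgt$path, legs)
}

#' Map a selection along one leg of an index map relationship
#'
#' The `SOURCE_TO_TARGET` leg composes the `order` leg (A to M) with the
#' `indexes` leg (M to B); sentinel entries on the stacking axis are
#' dropped and duplicate target indices deduplicated.
#'
#' @param imr An index map relationship bundle.
#' @param leg One of `"SOURCE_TO_MAP"`, `"MAP_TO_SOURCE"`,
#'   `"MAP_TO_TARGET"`, `"SOURCE_TO_TARGET"`.
#' @param sel A [selection()] on the leg's source.
#' @return The mapped selection.
#' @export
imr_map <- function(imr, leg, sel) {
  stopifnot(inherits(imr, "neurofmt_imr"))
  leg <- match.arg(leg, names(IMR_POSTFIXES))
  if (leg == "SOURCE_TO_TARGET") {
    through <- map_selection(imr$legs$SOURCE_TO_MAP, sel)
    return(map_selection(imr$legs$MAP_TO_TARGET, through))
  }
  if (is.null(imr$legs[[leg]]))
    stop(sprintf("index map relationship has no '%s' leg", leg))
  map_selection(imr$legs[[leg]], sel)
}

#' Locate index map relationships on an object
#'
#' Groups co-named postfixed relationship attributes into bundles. The
#' object may be the chain's source A (carrying the `SOURCE_TO_MAP` leg)
#' or its map M (carrying the `MAP_TO_*` legs). Bundles missing a
#' required leg are reported as findings (attribute `"findings"` of the
#' result), not returned.
#'
#' @param x Handle (or file path) of the object.
#' @return List of index map relationship bundles, with a `findings`
#'   attribute (data frame) describing incomplete bundles.
#' @export
get_index_map_relationships <- function(x) {
  h <- as_handle(x)
  rels <- list_relationship_attributes(h)
  findings <- no_findings()
  bundles <- list()
  base_of <- function(nm) {
    for (pf in IMR_POSTFIXES)
      if (endsWith(nm, pf))
        return(substring(nm, 1, nchar(nm) - nchar(pf)))
    NULL
  }
  bases <- unique(unlist(lapply(rels, function(r) base_of(r$name))))
  for (b in bases) {
    # locate A and M for this base
    here <- Filter(function(r) identical(base_of(r$name), b), rels)
    names(here) <- vapply(here, function(r) {
      for (nm in names(IMR_POSTFIXES))
        if (endsWith(r$name, IMR_POSTFIXES[[nm]])) return(nm)
      ""
    }, character(1))
    if (!is.null(here$SOURCE_TO_MAP)) {
      a_path <- h$path
      m <- resolve_target(here$SOURCE_TO_MAP)
      m_path <- m$path; m_file <- m$file
    } else if (!is.null(here$MAP_TO_SOURCE) ||
               !is.null(here$MAP_TO_TARGET)) {
      m_path <- h$path; m_file <- h$file
      src <- if (!is.null(here$MAP_TO_SOURCE))
        resolve_target(here$MAP_TO_SOURCE) else NULL
      a_path <- if (is.null(src)) NA_character_ else src$path
    } else next
    legs <- list()
    collect <- function(file, path) {
      for (r in list_relationship_attributes(
             new_handle(file, path, "dataset")))
        if (identical(base_of(r$name), b)) {
          for (nm in names(IMR_POSTFIXES))
            if (endsWith(r$name, IMR_POSTFIXES[[nm]])) legs[[nm]] <<- r
        }
    }
    if (!is.na(a_path)) collect(h$file, a_path)
    collect(m_file, m_path)
    required <- c("SOURCE_TO_MAP", "MAP_TO_SOURCE", "MAP_TO_TARGET")
    missing <- setdiff(required, names(legs))
    if (length(missing)) {
      findings <- rbind(findings, finding(
        h$path, "incomplete-imr-bundle", "warning",
        sprintf("bundle '%s' is missing leg(s): %s", b,
                paste(missing, collapse = ", "))))
      next
    }
    tgt <- resolve_target(legs$MAP_TO_TARGET)
    bundles[[length(bundles) + 1L]] <-
      new_imr(h$file, b, a_path, m_path, tgt$path, legs)
  }
  attr(bundles, "findings") <- findings
  bundles
}
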