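#' Selections
#'
#' A selection names elements of a dataset per axis (a point, a half-open
#' range, or an explicit index list) or members of a group (by name or by
#' ordinal in alphabetic member order). Selections are the operands of
#' [map_selection()]; all indices are 0-based and ranges half-open
#' `[start, stop)`.
#'
#' @param ... One selector per axis, built with [sel_point()],
#'   [sel_range()], [sel_indices()], [sel_all()], or (for groups)
#'   [sel_members()]. Bare integers are promoted to point selectors.
#' @return A selection object.
#' @export
selection <- function(...) {
  sels <- lapply(list(...), function(s) {
    if (inherits(s, "neurofmt_selector")) return(s)
    if (is.numeric(s) && length(s) == 1) return(sel_point(s))
    if (is.numeric(s)) return(sel_indices(s))
    stop("selector must be numeric or built with a sel_*() constructor")
  })
  structure(list(selectors = sels), class = "neurofmt_selection")
}

new_selector <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "neurofmt_selector")
}

#' @rdname selection
#' @param i 0-based element index.
#' @export
sel_point <- function(i) new_selector("point", list(value = as.double(i)))

#' @rdname selection
#' @param start,stop Half-open 0-based range bounds.
#' @export
sel_range <- function(start, stop) {
  stopifnot(stop >= start)
  new_selector("range", list(start = as.double(start),
                             stop = as.double(stop)))
}

#' @rdname selection
#' @param indices Explicit 0-based index vector.
#' @export
sel_indices <- function(indices) {
  new_selector("indices", list(indices = as.double(indices)))
}

#' @rdname selection
#' @export
sel_all <- function() new_selector("all", list())

#' @rdname selection
#' @param members Character vector of group member names.
#' @export
sel_members <- function(members) {
  new_selector("members", list(members = as.character(members)))
}

is_range_selector <- function(s) s$kind == "range"

# 0-based indices selected by one selector on one axis of length `extent`
selector_indices <- function(s, extent) {
  idx <- switch(s$kind,
                point = s$value,
                range = if (s$stop > s$start) seq(s$start, s$stop - 1) else
                  numeric(),
                indices = s$indices,
                all = seq_len(extent) - 1,
                stop("selector kind '", s$kind,
                     "' is not an index selector"))
  if (length(idx) && (min(idx) < 0 || max(idx) >= extent))
    stop(sprintf("selection out of bounds: axis extent %d, indices [%s]",
                 extent, paste(range(idx), collapse = ", ")))
  as.double(idx)
}

#' Materialize a selection as 0-based indices
#'
#' For a one-axis selection returns an index vector; for a multi-axis
#' selection returns a matrix with one 0-based index tuple per row.
#'
#' @param sel A selection (or point-set) object.
#' @param dims Axis extents used for bounds checks and `sel_all()`.
#' @return Numeric vector or matrix of 0-based indices.
#' @export
selection_indices <- function(sel, dims) {
  if (inherits(sel, "neurofmt_pointset")) return(sel$points)
  stopifnot(inherits(sel, "neurofmt_selection"))
  if (length(sel$selectors) != length(dims))
    stop(sprintf("selection has %d axes, dataset has %d",
                 length(sel$selectors), length(dims)))
  per_axis <- Map(selector_indices, sel$selectors, dims)
  if (length(dims) == 1) return(per_axis[[1]])
  grid <- do.call(expand.grid, rev(per_axis))  # row-major over axes
  m <- as.matrix(grid[, rev(seq_along(per_axis)), drop = FALSE])
  dimnames(m) <- NULL
  m
}

# a set of index tuples on a rank >= 1 target; rows are 0-based tuples
pointset <- function(points) {
  storage.mode(points) <- "double"
  points <- unique(points)
  if (nrow(points))
    points <- points[do.call(order, as.data.frame(points)), , drop = FALSE]
  structure(list(points = points), class = "neurofmt_pointset")
}

#' @export
print.neurofmt_pointset <- function(x, ...) {
  cat(sprintf("<point-set selection> %d point(s), rank %d\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' @export
print.neurofmt_selection <- function(x, ...) {
  desc <- vapply(x$selectors, function(s) switch(
    s$kind,
    point = sprintf("%g", s$value),
    range = sprintf("[%g,%g)", s$start, s$stop),
    indices = sprintf("{%s}", paste(s$indices, collapse = ",")),
    all = ":",
    members = sprintf("{%s}", paste(s$members, collapse = ","))),
    character(1))
  cat("<selection> ", paste(desc, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# canonical 1-D result: deduplicated ascending; contiguous runs become a
# half-open range selector
canonical_index_selection <- function(idx) {
  idx <- sort(unique(as.double(idx)))
  if (length(idx) && length(idx) == (max(idx) - min(idx) + 1)) {
    selection(sel_range(min(idx), max(idx) + 1))
  } else {
    selection(sel_indices(idx))
  }
}

# tuple matrix -> pointset, or 1-D canonical selection when rank 1
canonical_result <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (ncol(points) == 1) canonical_index_selection(points[, 1])
  else pointset(points)
}

#' Bounding block of a mapped point set
#'
#' Convenience for rectangular mapped regions: returns per-axis
#' `[min, max]` bounds and whether the points fill that block exactly.
#'
#' @param ps A point-set selection.
#' @return List with `bounds` (2 x rank matrix), `side` (per-axis side
#'   lengths), and `full` (does the set fill the bounding block?).
#' @export
pointset_block <- function(ps) {
  stopifnot(inherits(ps, "neurofmt_pointset"))
  b <- apply(ps$points, 2, range)
  side <- b[2, ] - b[1, ] + 1
  list(bounds = b, side = side, full = prod(side) == nrow(ps$points))
}
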