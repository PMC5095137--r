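#' @useDynLib neurofmt, .registration = TRUE
#' @importFrom jsonlite toJSON fromJSON write_json
#' @importFrom stats rnorm runif
#' @importFrom utils head tail
NULL

# Thin R wrappers over the bundled HDF5 glue (src/h5glue.c).
#
# Conventions at this layer:
#  * dim vectors are in R (column-major) order; the C layer reverses them so
#    that no transposition of data is ever needed,
#  * axis numbers and indices are 0-based, ranges half-open [start, stop);
#    this is the package-wide convention for everything that names an axis
#    or an element position, mirroring how selections are written on disk.

h5_create_file <- function(path, overwrite = FALSE) {
  invisible(.Call(C_h5_file_create, path, as.logical(overwrite)))
}

h5_is_hdf5 <- function(path) {
  file.exists(path) && .Call(C_h5_is_hdf5, path)
}

h5_create_group <- function(file, path) {
  invisible(.Call(C_h5_group_create, file, path))
}

h5_link_exists <- function(file, path) .Call(C_h5_link_exists, file, path)

h5_object_exists <- function(file, path) .Call(C_h5_object_exists, file, path)

h5_obj_kind <- function(file, path) .Call(C_h5_obj_kind, file, path)

h5_ls <- function(file, path = "/") sort(.Call(C_h5_ls, file, path))

h5_link_kind <- function(file, path) .Call(C_h5_link_kind, file, path)

h5_external_link_target <- function(file, path) {
  v <- .Call(C_h5_external_link_target, file, path)
  list(file = v[[1]], path = v[[2]])
}

h5_create_external_link <- function(file, link_path, target_file, target_path) {
  invisible(.Call(C_h5_create_external_link, file, link_path,
                  target_file, target_path))
}

h5_delete <- function(file, path) invisible(.Call(C_h5_delete_link, file, path))

#' @noRd
#' @param unlimited logical vector (recycled) marking extendible axes
h5_write_dataset <- function(file, path, data, dims = NULL, unlimited = FALSE,
                             chunks = NULL) {
  if (is.null(dims)) dims <- if (is.null(dim(data))) length(data) else dim(data)
  unlimited <- rep_len(as.logical(unlimited), length(dims))
  if (is.logical(data)) data <- as.integer(data)
  stopifnot(length(data) == prod(dims))
  invisible(.Call(C_h5_make_dataset, file, path, data, as.double(dims),
                  unlimited, if (is.null(chunks)) NULL else as.double(chunks)))
}

h5_read_dataset <- function(file, path) .Call(C_h5_read_dataset, file, path)

h5_dataset_dims <- function(file, path) .Call(C_h5_dataset_dims, file, path)

h5_set_extent <- function(file, path, dims) {
  invisible(.Call(C_h5_set_extent, file, path, as.double(dims)))
}

# start is 0-based, in R axis order
h5_write_hyperslab <- function(file, path, data, start, count) {
  if (is.logical(data)) data <- as.integer(data)
  stopifnot(length(data) == prod(count))
  invisible(.Call(C_h5_write_hyperslab, file, path, data,
                  as.double(start), as.double(count)))
}

h5_write_attr <- function(file, path, name, value) {
  invisible(.Call(C_h5_write_attr, file, path, name, value))
}

h5_read_attr <- function(file, path, name) .Call(C_h5_read_attr, file, path, name)

h5_attr_exists <- function(file, path, name) {
  .Call(C_h5_attr_exists, file, path, name)
}

h5_delete_attr <- function(file, path, name) {
  invisible(.Call(C_h5_attr_delete, file, path, name))
}

h5_ls_attrs <- function(file, path) sort(.Call(C_h5_ls_attrs, file, path))

h5_ds_set_scale <- function(file, scale_path, scale_name) {
  invisible(.Call(C_h5_ds_set_scale, file, scale_path, scale_name))
}

h5_ds_attach <- function(file, scale_path, data_path, axis) {
  invisible(.Call(C_h5_ds_attach, file, scale_path, data_path,
                  as.integer(axis)))
}

h5_ds_is_attached <- function(file, scale_path, data_path, axis) {
  .Call(C_h5_ds_is_attached, file, scale_path, data_path, as.integer(axis))
}

# join HDF5 paths, normalizing duplicate slashes
h5_path_join <- function(...) {
  p <- paste(c(...), collapse = "/")
  p <- gsub("/+", "/", p)
  if (p != "/" && endsWith(p, "/")) p <- substr(p, 1L, nchar(p) - 1L)
  if (!startsWith(p, "/")) p <- paste0("/", p)
  p
}

h5_parent_path <- function(path) {
  if (path == "/") return("/")
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  if (length(parts) <= 1L) "/" else h5_path_join(head(parts, -1L))
}

h5_basename <- function(path) {
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  if (length(parts) == 0L) "/" else tail(parts, 1L)
}
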