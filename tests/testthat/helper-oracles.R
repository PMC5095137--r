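# Independent brute-force oracles for selection mapping. These scan and
# gather linearly over plain R vectors and never touch the package's
# mapping code; results are canonicalized to sorted unique 0-based
# indices for comparison.

oracle_map <- function(type, svals, tvals, idx0, ranged = FALSE) {
  picked <- svals[idx0 + 1]
  out <- switch(
    type,
    order = ,
    equivalent = {
      if (length(idx0) && max(idx0) >= length(tvals))
        stop("out of bounds")
      idx0
    },
    indexes = {
      v <- picked[picked >= 0]
      if (length(v) && max(v) >= length(tvals)) stop("out of bounds")
      v
    },
    shared_encoding = ,
    indexes_values = which(tvals %in% picked) - 1,
    shared_ascending_encoding = {
      if (ranged && length(picked))
        which(tvals >= min(picked) & tvals <= max(picked)) - 1
      else
        which(tvals %in% picked) - 1
    },
    stop("no oracle for type ", type))
  sort(unique(out))
}

# oracle for the rectangular index-map layout: returns the deduplicated
# target tuples of a set of source cells, read straight out of the array
oracle_imr_targets <- function(M, cells, trank) {
  # M: array (spatial..., [index axis], [stacking axis]); cells: matrix of
  # 0-based spatial tuples; trank: rank of the target
  n_spatial <- ncol(cells)
  extra <- length(dim(M)) - n_spatial
  tuples <- NULL
  for (r in seq_len(nrow(cells))) {
    args <- c(as.list(cells[r, ] + 1),
              rep(list(TRUE), extra))
    slab <- do.call(`[`, c(list(M), args))
    tup <- if (extra == 2 || (extra == 1 && trank > 1))
      t(matrix(slab, nrow = trank)) else matrix(slab, ncol = 1)
    tup <- tup[apply(tup, 1, function(v) all(v >= 0)), , drop = FALSE]
    tuples <- rbind(tuples, tup)
  }
  if (is.null(tuples) || nrow(tuples) == 0)
    return(matrix(numeric(), ncol = max(trank, 1)))
  tuples <- unique(tuples)
  tuples[do.call(order, as.data.frame(tuples)), , drop = FALSE]
}

# draw a random selection on a 1-D extent; returns list(sel=, idx0=, ranged=)
random_selection_1d <- function(extent) {
  kind <- sample(c("point", "range", "indices"), 1)
  if (kind == "point") {
    i <- sample.int(extent, 1) - 1
    list(sel = selection(sel_point(i)), idx0 = i, ranged = FALSE)
  } else if (kind == "range") {
    a <- sample.int(extent, 1) - 1
    b <- sample(a:extent, 1)
    idx0 <- if (b > a) a:(b - 1) else numeric()
    list(sel = selection(sel_range(a, b)), idx0 = idx0, ranged = TRUE)
  } else {
    n <- sample.int(min(extent, 8), 1)
    idx0 <- sample.int(extent, n) - 1
    list(sel = selection(sel_indices(idx0)), idx0 = idx0, ranged = FALSE)
  }
}

mapped_indices <- function(mapped, extent) {
  sort(unique(selection_indices(mapped, extent)))
}

# random meta-valid spec documents for the round-trip property
random_spec_doc <- function(depth = 2) {
  rand_name <- function() paste0(sample(letters, 6, TRUE), collapse = "")
  rand_attr <- function() {
    if (runif(1) < 0.5)
      attribute_spec(attribute = rand_name(),
                     value = if (runif(1) < 0.5) rand_name(),
                     optional = runif(1) < 0.5, description = rand_name())
    else
      attribute_spec(prefix = rand_name(), optional = runif(1) < 0.5)
  }
  rand_rel <- function() {
    relationship_spec(rand_name(),
                      sample(neurofmt:::RELATIONSHIP_TYPES, 1),
                      paste0("/", rand_name()),
                      source_axes = if (runif(1) < 0.5) 0:1,
                      target_axes = if (runif(1) < 0.5) NULL else NULL,
                      optional = runif(1) < 0.5)
  }
  rand_dataset <- function() {
    d <- dataset_spec(dataset = rand_name(), primary = runif(1) < 0.5,
                      description = rand_name())
    for (k in seq_len(sample(0:2, 1))) d <- add_attribute(d, rand_attr())
    if (runif(1) < 0.4)
      d <- add_dimension(d, dimension_spec(rand_name(), "ms", rand_name(),
                                           sample(0:2, 1)))
    if (runif(1) < 0.3) d <- attach_child_spec(d, rand_rel())
    d
  }
  g <- if (runif(1) < 0.5) group_spec(group = rand_name())
       else group_spec(prefix = rand_name())
  for (k in seq_len(sample(0:3, 1))) g <- add_dataset(g, rand_dataset())
  for (k in seq_len(sample(0:2, 1))) g <- add_attribute(g, rand_attr())
  if (depth > 0 && runif(1) < 0.6)
    g <- attach_child_spec(g, random_spec_doc(depth - 1), rand_name())
  if (runif(1) < 0.3)
    g <- attach_child_spec(g, managed_ref(rand_name(),
                                          optional = runif(1) < 0.5))
  g
}

# equality of spec documents up to class attributes and integer/double
# storage of numbers (JSON does not distinguish the two)
spec_normalize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, spec_normalize)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.numeric(x)) as.double(x) else x
}

expect_spec_equal <- function(a, b) {
  expect_identical(spec_normalize(a), spec_normalize(b))
}
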