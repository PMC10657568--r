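#' Construct a landmark shape dataset
#'
#' A shape dataset holds `n` two-dimensional landmark configurations
#' that share the same number `k` of points, where landmark `i` marks
#' the same anatomical locus in every configuration.  Configurations are
#' stored as a `k x 2 x n` array (the convention of the major
#' morphometric packages), together with per-configuration ids, image
#' names, optional digitizing scale factors, and an optional label table
#' carrying grouping factors (species, site, colony, replicate).
#'
#' @param coords numeric `k x 2 x n` array of landmark coordinates, or a
#'   list of `k x 2` matrices.
#' @param ids character vector of unique configuration ids; defaults to
#'   `dimnames(coords)[[3]]` or `"cfg1"`, `"cfg2"`, ...
#' @param image character vector of source image names (optional).
#' @param scale numeric vector of digitizing scale factors; `NA` where
#'   none was recorded.
#' @param labels data frame with an `id` column plus grouping columns
#'   (typically `species`, `site`, `colony`, `replicate_id`), or `NULL`.
#' @return an object of class `shape_dataset` with elements `coords`,
#'   `ids`, `image`, `scale`, `labels`, `k` and `n`.
#' @seealso [read_tps()], [simulate_shapes()], [gpa()]
#' @export
shape_dataset <- function(coords, ids = NULL, image = NULL, scale = NULL,
                          labels = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) > 1L)
      stop("all configurations must have the same number of landmarks; found k = ",
           paste(unique(ks), collapse = ", "))
    coords <- array(unlist(coords), dim = c(ks[1L], 2L, length(ks)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 2L)
    stop("'coords' must be a k x 2 x n array of 2-D landmarks")
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (k < 3L) stop("configurations need at least 3 landmarks (k >= 3)")
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  if (is.null(ids)) ids <- dimnames(coords)[[3L]]
  if (is.null(ids)) ids <- paste0("cfg", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("'ids' must have one entry per configuration")
  if (anyDuplicated(ids))
    stop("configuration ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(image) && length(image) != n)
    stop("'image' must have one entry per configuration")
  if (is.null(scale)) scale <- rep(NA_real_, n)
  if (length(scale) != n) stop("'scale' must have one entry per configuration")
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!"id" %in% names(labels)) stop("label table must have an 'id' column")
    labels <- labels[match(ids, labels$id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  dimnames(coords) <- list(NULL, c("x", "y"), ids)
  structure(list(coords = coords, ids = ids, image = image,
                 scale = as.numeric(scale), labels = labels, k = k, n = n),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset: ", x$n, " configurations of ", x$k, " landmarks\n",
      sep = "")
  if (!is.null(x$labels)) {
    fac <- setdiff(names(x$labels), "id")
    for (f in fac) {
      lv <- unique(x$labels[[f]])
      cat("  ", f, ": ", length(lv), " level(s)\n", sep = "")
    }
  }
  invisible(x)
}

#' Attach a label table to a shape dataset
#'
#' Joins a label table (columns `id`, `species`, `site`, `colony`,
#' `replicate_id`; extra columns are kept) onto a dataset by
#' configuration id.  Optionally derives a colony id from the stored
#' image names with a regular expression, which is how colony membership
#' is usually encoded when images are named after voucher codes (for
#' example a leading `"WW\\d+"`).
#'
#' @param dataset a [shape_dataset()].
#' @param labels data frame with an `id` column, or path to a CSV file.
#' @param colony_regex optional regular expression; when given and the
#'   dataset has image names, the first match in each image name is used
#'   to fill a `colony` column (existing values are kept).
#' @return the dataset with `$labels` set.
#' @export
attach_labels <- function(dataset, labels, colony_regex = NULL) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (is.character(labels) && length(labels) == 1L)
    labels <- read.csv(labels, stringsAsFactors = FALSE)
  labels <- as.data.frame(labels)
  if (!"id" %in% names(labels)) stop("label table must have an 'id' column")
  missing_ids <- setdiff(dataset$ids, labels$id)
  if (length(missing_ids))
    stop("label table misses configuration id(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  labels <- labels[match(dataset$ids, labels$id), , drop = FALSE]
  if (!is.null(colony_regex) && !is.null(dataset$image)) {
    m <- regmatches(dataset$image, regexpr(colony_regex, dataset$image))
    col <- rep(NA_character_, dataset$n)
    col[grepl(colony_regex, dataset$image)] <- m
    if (is.null(labels$colony)) labels$colony <- col
    else labels$colony[is.na(labels$colony)] <- col[is.na(labels$colony)]
  }
  rownames(labels) <- NULL
  dataset$labels <- labels
  dataset
}

#' Subset a shape dataset
#'
#' @param x a [shape_dataset()].
#' @param i logical, integer or character (id) index of configurations.
#' @param ... ignored.
#' @return the subset as a `shape_dataset`.
#' @export
`[.shape_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  shape_dataset(x$coords[, , i, drop = FALSE], ids = x$ids[i],
                image = if (!is.null(x$image)) x$image[i],
                scale = x$scale[i],
                labels = if (!is.null(x$labels)) x$labels[i, , drop = FALSE])
}

#' Construct a semilandmark slider specification
#'
#' Each slider is defined by a triplet `(before, slider, after)` of
#' landmark indices: during superimposition the middle point may slide
#' along the chord joining its two neighbours.  Chained triplets such as
#' `(1,2,3)` and `(2,3,4)` describe consecutive semilandmarks on one
#' curve.
#'
#' @param triplets integer matrix (or data frame) with three columns
#'   `before`, `slider`, `after`; may have zero rows.
#' @param k number of landmarks in the configurations the spec applies to.
#' @return object of class `sliders_spec`: the triplet matrix with
#'   attributes `k` and `sliders` (the sorted set of sliding indices).
#' @export
sliders_spec <- function(triplets, k) {
  triplets <- as.matrix(triplets)
  if (length(triplets) == 0L) triplets <- matrix(integer(0), 0L, 3L)
  if (ncol(triplets) != 3L) stop("slider triplets must have 3 columns")
  storage.mode(triplets) <- "integer"
  colnames(triplets) <- c("before", "slider", "after")
  if (nrow(triplets)) {
    if (any(triplets < 1L | triplets > k))
      stop("slider indices must lie in [1..k] with k = ", k)
    bad <- triplets[, 2L] == triplets[, 1L] | triplets[, 2L] == triplets[, 3L]
    if (any(bad))
      stop("slider index equals one of its neighbours in triplet(s) ",
           paste(which(bad), collapse = ", "))
    if (anyDuplicated(triplets[, 2L]))
      stop("each landmark may appear as a slider at most once")
  }
  structure(triplets, class = "sliders_spec", k = as.integer(k),
            sliders = sort(unique(triplets[, 2L])))
}

#' @export
print.sliders_spec <- function(x, ...) {
  cat("Sliders: ", nrow(x), " semilandmark(s) of k = ", attr(x, "k"),
      " landmarks\n", sep = "")
  invisible(x)
}

n_sliders <- function(spec) if (is.null(spec)) 0L else nrow(spec)

#' Construct an aligned sequence set
#'
#' @param sequences named character vector of equal-length, upper-case
#'   sequences over `A`, `C`, `G`, `T`, `N`, `-` (other IUPAC ambiguity
#'   codes are recoded to `N`).
#' @param ids ids; default names of `sequences`.
#' @return object of class `sequence_set`: list with `ids`, `sequences`
#'   (character vector), `length`.
#' @export
sequence_set <- function(sequences, ids = names(sequences)) {
  ids <- ids   # force before names are dropped below
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("sequences are not aligned: lengths ",
         paste(unique(lens), collapse = ", "))
  # recode non-ACGT/gaps to N; reject anything that is not IUPAC-like
  sequences <- gsub("[RYSWKMBDHV?]", "N", sequences)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  names(sequences) <- ids
  structure(list(ids = ids, sequences = sequences,
                 length = if (length(lens)) lens[1L] else 0L),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("Aligned sequence set: ", length(x$ids), " sequences of length ",
      x$length, "\n", sep = "")
  invisible(x)
}
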