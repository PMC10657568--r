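#' Read landmark configurations from a TPS file
#'
#' Parses the TPS landmark format produced by the tpsUtil/tpsDig family
#' of tools.  Each record starts with an `LM=<count>` line followed by
#' that many `x y` coordinate lines; optional `CURVES=<ncurves>` /
#' `POINTS=<npoints>` blocks hold semilandmark curves, and optional
#' `IMAGE=`, `ID=` and `SCALE=` lines carry metadata.  Curve points are
#' appended after the fixed landmarks in file order, so the total point
#' count is `k = fixed + semilandmarks`; both the flattened dialect (all
#' points under `LM=`) and the `CURVES=` dialect are accepted and
#' normalized to the flattened representation.  Keys are matched
#' case-insensitively and CRLF line endings are tolerated.
#'
#' @param path path to a TPS text file.
#' @param apply_scale if `TRUE` (default) coordinates of records with a
#'   `SCALE=` factor are multiplied by it, putting them in physical
#'   units; records lacking a scale keep pixel units and are flagged in
#'   the returned `scale` vector (`NA`).
#' @param invert_y if `TRUE`, y coordinates are negated.  Digitizers
#'   that work in image coordinates have y increasing downward; flipping
#'   restores the mathematical y-up convention.
#' @return a [shape_dataset()] (without labels).  The per-record count
#'   of fixed landmarks is stored in the `"n_fixed"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1",
#'              "IMAGE=a.jpg", "ID=1", "SCALE=0.5"), tf)
#' d <- read_tps(tf)
#' d$coords[, , 1]   # scaled by 0.5
#' @export
read_tps <- function(path, apply_scale = TRUE, invert_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  if (!length(starts)) {
    if (!length(lines))
      return(empty_shape_dataset())
    stop("no LM= records found in ", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    recs[[r]] <- parse_tps_record(block, r, path)
  }
  ks <- vapply(recs, function(z) nrow(z$points), integer(1))
  if (length(unique(ks)) > 1L)
    stop("inconsistent landmark counts across records in ", path, ": ",
         paste(unique(ks), collapse = ", "))
  ids <- vapply(recs, function(z) z$id, character(1))
  if (anyDuplicated(ids) || all(ids == ""))
    ids <- paste0("cfg", seq_along(recs))
  scales <- vapply(recs, function(z) z$scale, numeric(1))
  coords <- array(0, dim = c(ks[1L], 2L, length(recs)))
  for (r in seq_along(recs)) {
    p <- recs[[r]]$points
    if (apply_scale && !is.na(scales[r])) p <- p * scales[r]
    if (invert_y) p[, 2L] <- -p[, 2L]
    coords[, , r] <- p
  }
  ds <- shape_dataset(coords, ids = ids,
                      image = vapply(recs, function(z) z$image, character(1)),
                      scale = scales)
  attr(ds, "n_fixed") <- vapply(recs, function(z) z$n_fixed, integer(1))
  if (any(is.na(scales)))
    attr(ds, "unscaled") <- ds$ids[is.na(scales)]
  ds
}

parse_tps_record <- function(block, r, path) {
  key_val <- function(key) {
    i <- grep(paste0("^", key, "="), block, ignore.case = TRUE)
    if (length(i)) sub(paste0("(?i)^", key, "="), "", block[i[1L]], perl = TRUE)
    else NA_character_
  }
  n_lm <- suppressWarnings(as.integer(key_val("LM")))
  if (is.na(n_lm) || n_lm < 0L)
    stop("record ", r, " in ", path, ": malformed LM= line")
  is_coord <- grepl("^[-+0-9.]", block)
  parse_coords <- function(idx, what) {
    xy <- strsplit(block[idx], "[ \t,]+")
    ok <- lengths(xy) >= 2L
    if (!all(ok))
      stop("record ", r, " in ", path, ": malformed coordinate line in ", what)
    m <- t(vapply(xy, function(v) as.numeric(v[1:2]), numeric(2)))
    if (any(!is.finite(m)))
      stop("record ", r, " in ", path, ": non-numeric coordinates in ", what)
    m
  }
  pos <- 2L
  if (n_lm > 0L) {
    idx <- pos:(pos + n_lm - 1L)
    if (max(idx) > length(block) || !all(is_coord[idx]))
      stop("record ", r, " in ", path, ": LM=", n_lm,
           " but fewer coordinate lines follow")
    fixed <- parse_coords(idx, "landmarks")
    pos <- pos + n_lm
  } else fixed <- matrix(numeric(0), 0L, 2L)
  curves <- list()
  if (pos <= length(block) && grepl("^CURVES=", block[pos], ignore.case = TRUE)) {
    n_curves <- as.integer(sub("(?i)^CURVES=", "", block[pos], perl = TRUE))
    pos <- pos + 1L
    for (ci in seq_len(n_curves)) {
      if (pos > length(block) || !grepl("^POINTS=", block[pos], ignore.case = TRUE))
        stop("record ", r, " in ", path, ": expected POINTS= for curve ", ci)
      np <- as.integer(sub("(?i)^POINTS=", "", block[pos], perl = TRUE))
      pos <- pos + 1L
      idx <- pos:(pos + np - 1L)
      if (max(idx) > length(block) || !all(is_coord[idx]))
        stop("record ", r, " in ", path, ": POINTS=", np,
             " but fewer coordinate lines follow in curve ", ci)
      curves[[ci]] <- parse_coords(idx, paste0("curve ", ci))
      pos <- pos + np
    }
  }
  points <- rbind(fixed, do.call(rbind, curves))
  if (nrow(points) == 0L)
    stop("record ", r, " in ", path, ": no coordinates")
  id <- key_val("ID"); image <- key_val("IMAGE")
  list(points = points, n_fixed = n_lm,
       id = if (is.na(id)) "" else id,
       image = if (is.na(image)) "" else image,
       scale = suppressWarnings(as.numeric(key_val("SCALE"))))
}

empty_shape_dataset <- function() {
  structure(list(coords = array(0, c(0L, 2L, 0L)), ids = character(0),
                 image = character(0), scale = numeric(0), labels = NULL,
                 k = 0L, n = 0L),
            class = "shape_dataset")
}

#' Write a shape dataset to a TPS file
#'
#' Writes the flattened TPS dialect: one `LM=<k>` record per
#' configuration with all points (fixed landmarks followed by
#' semilandmarks) as coordinate lines, plus `IMAGE=`, `ID=` and
#' `SCALE=` lines where available.  Coordinates are written with six
#' decimals, so `read_tps(write_tps(x))` reproduces `x` to 1e-6.
#'
#' @param dataset a [shape_dataset()].
#' @param path output file path.
#' @param digits decimal places for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path, digits = 6) {
  stopifnot(inherits(dataset, "shape_dataset"))
  out <- character(0)
  for (i in seq_len(dataset$n)) {
    p <- dataset$coords[, , i]
    rec <- c(paste0("LM=", dataset$k),
             sprintf(paste0("%.", digits, "f %.", digits, "f"),
                     p[, 1L], p[, 2L]))
    if (!is.null(dataset$image) && nzchar(dataset$image[i]))
      rec <- c(rec, paste0("IMAGE=", dataset$image[i]))
    rec <- c(rec, paste0("ID=", dataset$ids[i]))
    if (!is.na(dataset$scale[i]))
      rec <- c(rec, paste0("SCALE=", format(dataset$scale[i], digits = 12)))
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a semilandmark sliders file
#'
#' A sliders file lists one `before slider after` triplet of landmark
#' indices per line (whitespace- or comma-separated; a header line is
#' skipped if present).  An empty file yields a spec with zero sliders,
#' in which case superimposition treats all points as fixed.
#'
#' @param path path to the sliders file.
#' @param k number of landmarks the indices refer to.
#' @return a [sliders_spec()].
#' @export
read_sliders <- function(path, k) {
  if (!file.exists(path)) stop("sliders file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^[A-Za-z#]", lines)]  # drop header/comment lines
  if (!length(lines)) return(sliders_spec(matrix(integer(0), 0L, 3L), k))
  parts <- strsplit(lines, "[ \t,]+")
  if (any(lengths(parts) != 3L))
    stop("each sliders line must hold exactly 3 indices")
  trip <- t(vapply(parts, function(v) as.integer(v), integer(3)))
  if (any(is.na(trip))) stop("non-integer entry in sliders file ", path)
  sliders_spec(trip, k)
}

#' Write a sliders specification to a plain-text file
#'
#' @param sliders a [sliders_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sliders <- function(sliders, path) {
  writeLines(apply(unclass(sliders), 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Read an aligned FASTA file of barcodes
#'
#' Reads a FASTA alignment, upper-cases the sequences and enforces equal
#' lengths.  IUPAC ambiguity codes other than `N` are recoded to `N`;
#' characters outside `A`, `C`, `G`, `T`, `N`, `-` raise an error naming
#' the offending sequences.
#'
#' @param path path to a FASTA file.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) return(sequence_set(character(0)))
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  sequence_set(seqs, ids = names(dna))
}

#' Write an aligned sequence set as FASTA
#'
#' @param seqs a [sequence_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "sequence_set"))
  out <- as.vector(rbind(paste0(">", seqs$ids), seqs$sequences))
  writeLines(out, path)
  invisible(path)
}
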