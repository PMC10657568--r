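#' Uncorrected p-distance matrix of an aligned sequence set
#'
#' For every pair of sequences, the proportion of differing sites among
#' the sites where both sequences carry an unambiguous base (`A`, `C`,
#' `G` or `T`); sites with `N` or a gap in either sequence are excluded
#' from both numerator and denominator (pairwise deletion).  A pair with
#' zero comparable sites gets a missing (`NA`) distance and is flagged.
#'
#' @param seqs a [sequence_set()].
#' @return object of class `p_distance_matrix`: list with `ids`,
#'   `distance` (symmetric matrix, zero diagonal, `NA` where
#'   incomparable) and `comparable_sites` (counts per pair).
#' @export
p_distance_matrix <- function(seqs) {
  stopifnot(inherits(seqs, "sequence_set"))
  n <- length(seqs$ids)
  M <- do.call(rbind, strsplit(seqs$sequences, ""))
  good <- M %in% c("A", "C", "G", "T")
  dim(good) <- dim(M)
  D <- matrix(0, n, n, dimnames = list(seqs$ids, seqs$ids))
  Csites <- matrix(if (n) seqs$length else integer(0), n, n,
                   dimnames = list(seqs$ids, seqs$ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        comp <- good[i, ] & good[j, ]
        nc <- sum(comp)
        Csites[i, j] <- Csites[j, i] <- nc
        D[i, j] <- D[j, i] <-
          if (nc == 0L) NA_real_ else sum(M[i, comp] != M[j, comp]) / nc
      }
    }
  }
  if (anyNA(D))
    warning("pair(s) with zero comparable sites: distance set to NA")
  structure(list(ids = seqs$ids, distance = D, comparable_sites = Csites),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  n <- length(x$ids)
  cat("Uncorrected p-distance matrix: ", n, " sequences\n", sep = "")
  if (n > 1L) {
    up <- x$distance[upper.tri(x$distance)]
    cat(sprintf("  range %.4f-%.4f (%d missing)\n",
                min(up, na.rm = TRUE), max(up, na.rm = TRUE), sum(is.na(up))))
  }
  invisible(x)
}

as_full_dist <- function(dist) {
  if (inherits(dist, "p_distance_matrix")) dist
  else {
    m <- as.matrix(dist)
    structure(list(ids = rownames(m) %||% paste0("seq", seq_len(nrow(m))),
                   distance = m, comparable_sites = NULL),
              class = "p_distance_matrix")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Objective clustering at a distance threshold
#'
#' Groups sequences into the connected components of the graph that
#' links two sequences whenever their p-distance is at or below the
#' threshold (a single-linkage cut): every member of a multi-member
#' cluster matches at least one other member within the threshold.
#' Missing distances contribute no edge (and raise a warning), so
#' incomparable pairs can only be joined transitively.
#'
#' @param dist a [p_distance_matrix()] (or plain symmetric matrix).
#' @param threshold distance threshold in `[0, 1]`; joins are inclusive
#'   (`d <= threshold`).
#' @return object of class `cluster_partition`: list with `threshold`,
#'   `assignment` (named integer vector, clusters numbered by order of
#'   first appearance) and `n_clusters`.
#' @export
objective_cluster <- function(dist, threshold) {
  dist <- as_full_dist(dist)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  D <- dist$distance
  n <- nrow(D)
  if (anyNA(D))
    warning("missing distances treated as above threshold (no edge)")
  adj <- !is.na(D) & D <= threshold
  comp <- integer(n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cl <- cl + 1L
    queue <- s
    comp[s] <- cl
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  structure(list(threshold = threshold,
                 assignment = stats::setNames(comp, dist$ids),
                 n_clusters = cl),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Objective clustering at threshold %.3f: %d cluster(s)\n",
              x$threshold, x$n_clusters))
  invisible(x)
}

#' Single-linkage merge profile of a distance matrix
#'
#' Agglomerative single-linkage clustering of the full p-distance
#' matrix: merge heights are the minimum inter-cluster distances, so
#' cutting the profile at any height reproduces the threshold clustering
#' of [objective_cluster()] exactly.  Node heights are the percentage
#' thresholds at which clusters or sequences diverge.
#'
#' @param dist a [p_distance_matrix()] (complete, `n >= 2`).
#' @return object of class `merge_profile`: list with `hclust` (the
#'   [stats::hclust()] tree), `merges` (data frame of merge heights in
#'   non-decreasing order) and `ids`.
#' @export
merge_profile <- function(dist) {
  dist <- as_full_dist(dist)
  n <- nrow(dist$distance)
  if (n < 2L) stop("merge profile needs at least 2 sequences")
  if (anyNA(dist$distance))
    stop("merge profile needs a complete distance matrix")
  hc <- stats::hclust(stats::as.dist(dist$distance), method = "single")
  structure(list(hclust = hc,
                 merges = data.frame(step = seq_len(n - 1L),
                                     height = hc$height),
                 ids = dist$ids),
            class = "merge_profile")
}

#' @export
print.merge_profile <- function(x, ...) {
  cat("Single-linkage merge profile: ", length(x$ids), " sequences, ",
      nrow(x$merges), " merges\n", sep = "")
  cat("  divergence thresholds (%): ",
      paste(sprintf("%.1f", 100 * utils::head(sort(x$merges$height,
                                                   decreasing = TRUE), 5L)),
            collapse = ", "), " (top 5)\n", sep = "")
  invisible(x)
}

#' Cut a merge profile at a threshold
#'
#' @param profile a [merge_profile()].
#' @param threshold height at which to cut (inclusive: merges at exactly
#'   the threshold are kept).
#' @return a `cluster_partition` equal to
#'   `objective_cluster(dist, threshold)` on the same matrix.
#' @export
cut_profile <- function(profile, threshold) {
  stopifnot(inherits(profile, "merge_profile"))
  # cutree cuts strictly above h; inclusive joins need a nudge past ties
  memb <- stats::cutree(profile$hclust, h = threshold + 1e-12)
  # renumber by order of first appearance to match objective_cluster
  first <- !duplicated(memb)
  map <- stats::setNames(seq_len(sum(first)), memb[first])
  structure(list(threshold = threshold,
                 assignment = stats::setNames(as.integer(map[as.character(memb)]),
                                              profile$ids),
                 n_clusters = length(map)),
            class = "cluster_partition")
}

#' Export a merge profile as a Newick tree
#'
#' Branch lengths place every tip at depth equal to the root merge
#' height, so node depths correspond to the single-linkage divergence
#' thresholds.
#'
#' @param profile a [merge_profile()].
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when writing to a file.
#' @export
profile_newick <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "merge_profile"))
  phy <- ape::as.phylo(profile$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    invisible(txt)
  } else txt
}
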