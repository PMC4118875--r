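#' Rule for flagging isolated dendrogram branches
#'
#' A branch is "isolated" when it is small (at most `max_branch_size`
#' leaves) and joins the rest of the tree only above `height_factor`
#' times the median merge height. Spectra on such branches are treated as
#' outliers (e.g. shots that hit an inhomogeneous spot of the pellet).
#'
#' @param height_factor Multiplier on the median merge height (default 3).
#' @param max_branch_size Largest cluster still considered isolated
#'   (default 2).
#' @return A list of class `outlier_rule`.
#' @export
outlier_rule <- function(height_factor = 3, max_branch_size = 2) {
  stopifnot(height_factor > 0, max_branch_size >= 1)
  structure(list(height_factor = height_factor,
                 max_branch_size = as.integer(max_branch_size)),
            class = "outlier_rule")
}

#' Agglomerative clustering of spectra
#'
#' Hierarchical clustering of the rows of a spectra set over its valid
#' channels. Defaults — Euclidean distance, Ward (ward.D2) linkage — are
#' the standard choice for spectra and yield monotone merge heights.
#'
#' @param set A [spectra_set()].
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param leaf_labels Optional leaf names (default: row indices).
#' @return An object of class `libs_dendrogram` wrapping the
#'   [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(set, metric = "euclidean",
                                 linkage = "ward.D2", leaf_labels = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  n <- n_spectra(set)
  if (n < 2) stop("clustering requires at least two spectra", call. = FALSE)
  if (sum(set$valid_mask) < 1) stop("no valid channels", call. = FALSE)
  d <- stats::dist(valid_matrix(set), method = metric)
  hc <- stats::hclust(d, method = linkage)
  if (is.null(leaf_labels)) leaf_labels <- as.character(seq_len(n))
  hc$labels <- leaf_labels
  structure(list(hclust = hc, leaf_labels = leaf_labels, n = n),
            class = "libs_dendrogram")
}

#' @export
print.libs_dendrogram <- function(x, ...) {
  cat(sprintf("<libs_dendrogram> %d leaves, %d merges, heights %.3g-%.3g\n",
              x$n, x$n - 1L, min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Merge list of a dendrogram
#'
#' @param tree A `libs_dendrogram`.
#' @return A tibble with one row per merge: `node_a`, `node_b` (negative =
#'   leaf index, positive = earlier merge), `height`, and `size` (number
#'   of leaves under the merged node).
#' @export
dendrogram_merges <- function(tree) {
  hc <- tree$hclust
  m <- nrow(hc$merge)
  sizes <- integer(m)
  node_size <- function(v, sizes) ifelse(v < 0, 1L, sizes[v])
  for (i in seq_len(m)) {
    sizes[i] <- node_size(hc$merge[i, 1], sizes) + node_size(hc$merge[i, 2], sizes)
  }
  tibble::tibble(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                 height = hc$height, size = sizes)
}

#' @method tidy libs_dendrogram
#' @export
tidy.libs_dendrogram <- function(x, ...) dendrogram_merges(x)

#' Export a dendrogram as a Newick string
#'
#' @param tree A `libs_dendrogram`.
#' @return A Newick tree string (branch lengths from merge heights).
#' @export
dendrogram_to_newick <- function(tree) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy)
}

#' Flag spectra on isolated dendrogram branches
#'
#' Cuts the tree at `height_factor * median(merge heights)`; any
#' resulting cluster with at most `max_branch_size` leaves is an isolated
#' branch and its rows are flagged. If no cluster is larger than
#' `max_branch_size` (so there is no "rest of the data" to be isolated
#' from), nothing is flagged. Deterministic given tree and rule.
#'
#' @param tree A `libs_dendrogram` built over spectrum rows.
#' @param rule An [outlier_rule()].
#' @return Sorted integer vector of flagged row indices (possibly empty).
#' @export
detect_outliers <- function(tree, rule = outlier_rule()) {
  hc <- tree$hclust
  cut_h <- rule$height_factor * stats::median(hc$height)
  if (cut_h >= max(hc$height)) return(integer(0))
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  if (!any(sizes > rule$max_branch_size)) return(integer(0))
  small <- as.integer(names(sizes)[sizes <= rule$max_branch_size])
  sort(which(cl %in% small))
}

#' Per-class outlier detection
#'
#' Runs [hierarchical_cluster()] + [detect_outliers()] within each class
#' (the mean spectrum of a formulation should only be cleaned of that
#' formulation's own aberrant shots); a pooled variant over all rows is
#' available with `per_class = FALSE`. Classes with fewer than 3 rows are
#' left untouched.
#'
#' @param set A [spectra_set()].
#' @param rule An [outlier_rule()].
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @param per_class Detect within each class (default) or globally.
#' @return Sorted integer vector of flagged row indices in `set`.
#' @export
detect_outliers_by_class <- function(set, rule = outlier_rule(),
                                     metric = "euclidean",
                                     linkage = "ward.D2", per_class = TRUE) {
  if (!per_class) {
    return(detect_outliers(hierarchical_cluster(set, metric, linkage), rule))
  }
  flagged <- integer(0)
  for (cl in class_levels(set)) {
    rows <- which(set$labels == cl)
    if (length(rows) < 3) next
    tree <- hierarchical_cluster(set[rows], metric, linkage)
    flagged <- c(flagged, rows[detect_outliers(tree, rule)])
  }
  sort(flagged)
}

#' Per-class mean spectra
#'
#' Arithmetic mean spectrum of each formulation, computed after excluding
#' the given rows (typically the detected outliers).
#'
#' @param set A [spectra_set()].
#' @param exclude Row indices to drop before averaging.
#' @return A [spectra_set()] with one row per class, labelled by class,
#'   in the parent set's class order.
#' @export
class_mean_spectra <- function(set, exclude = integer(0)) {
  stopifnot(inherits(set, "spectra_set"))
  keep <- setdiff(seq_len(n_spectra(set)), exclude)
  means <- lapply(class_levels(set), function(cl) {
    rows <- intersect(which(set$labels == cl), keep)
    if (!length(rows)) {
      stop(sprintf("class '%s' has no spectra left after exclusion", cl),
           call. = FALSE)
    }
    colMeans(set$intensities[rows, , drop = FALSE])
  })
  spectra_set(set$wavelengths, do.call(rbind, means),
              labels = class_levels(set), valid_mask = set$valid_mask)
}

#' Class-similarity dendrogram
#'
#' Hierarchical clustering of the per-class mean spectra: formulations
#' whose mean spectra are most alike merge first.
#'
#' @param mean_set Output of [class_mean_spectra()] (>= 2 classes).
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @return A `libs_dendrogram` whose leaves are class names.
#' @export
class_similarity_dendrogram <- function(mean_set, metric = "euclidean",
                                        linkage = "ward.D2") {
  hierarchical_cluster(mean_set, metric, linkage, leaf_labels = mean_set$labels)
}
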