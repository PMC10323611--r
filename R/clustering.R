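#' Enumerate presence-pattern mixture classes
#'
#' Two spectra belong to the same mixture class if they are composed of the
#' same spectral components, i.e. share the K-bit presence pattern of their
#' unmixing coefficients. With K components there are at most 2^K classes
#' (512 for K = 9). Pixels whose pattern is all-zero form a flagged null
#' class that is excluded from the clustering tree.
#'
#' Each class records its mean spectral shape: member spectra are first
#' L2-normalized, then averaged (zero-norm members are dropped and
#' counted).
#'
#' @param presence A [binarize_presence()] result.
#' @param S The aligned N x L spectra matrix.
#' @return List of class `"mixture_classes"` with:
#'   `classes` (data.frame `pattern`, `count`, ordered by decreasing count,
#'   ties by pattern), `shapes` (C x L matrix of mean normalized shapes),
#'   `members` (list of member pixel indices per class), `assignment`
#'   (integer vector: class index per pixel, NA for null-class pixels),
#'   `null_count` (number of all-zero-pattern pixels), `k`.
#' @export
enumerate_classes <- function(presence, S) {
  stopifnot(inherits(presence, "presence_matrix"))
  S <- as.matrix(S)
  m <- presence$m
  stopifnot(nrow(S) == nrow(m))
  pat <- apply(m, 1, paste0, collapse = "")
  null_pat <- strrep("0", ncol(m))
  is_null <- pat == null_pat

  tab <- table(pat[!is_null])
  ord <- order(-as.integer(tab), names(tab))
  patterns <- names(tab)[ord]
  counts <- as.integer(tab)[ord]

  members <- lapply(patterns, function(p) which(pat == p))
  shapes <- t(vapply(members, function(idx) {
    class_mean_shape(S[idx, , drop = FALSE])
  }, numeric(ncol(S))))
  rownames(shapes) <- patterns

  assignment <- rep(NA_integer_, nrow(S))
  for (ci in seq_along(members)) assignment[members[[ci]]] <- ci

  structure(
    list(classes = data.frame(pattern = patterns, count = counts),
         shapes = shapes, members = members, assignment = assignment,
         null_count = sum(is_null), k = ncol(m)),
    class = "mixture_classes"
  )
}

#' @export
print.mixture_classes <- function(x, ...) {
  cat(sprintf(
    "%d mixture classes over %d components (max %d); %d null-class pixels\n",
    nrow(x$classes), x$k, 2^x$k, x$null_count
  ))
  invisible(x)
}

#' Mean L2-normalized spectral shape of a set of spectra
#'
#' Each spectrum is divided by its L2 norm, then the normalized spectra are
#' averaged; this captures spectral shape irrespective of signal magnitude.
#' Members with zero norm are dropped (their count is returned as an
#' attribute); if all members have zero norm the shape is undefined.
#'
#' @param spectra Matrix with one spectrum per row.
#' @return Mean normalized shape (length-L vector) with attribute
#'   `"dropped"` (number of zero-norm members).
#' @export
class_mean_shape <- function(spectra) {
  spectra <- as.matrix(spectra)
  nrm <- sqrt(rowSums(spectra^2))
  keep <- nrm > 0
  if (!any(keep)) stop("all member spectra have zero norm; mean shape undefined")
  shape <- colMeans(spectra[keep, , drop = FALSE] / nrm[keep])
  attr(shape, "dropped") <- sum(!keep)
  shape
}

#' Ward hierarchy over mixture classes
#'
#' Agglomerative hierarchical clustering of the class mean shapes with
#' Ward's minimum-variance linkage (each class enters as one unweighted
#' observation; Euclidean distance between mean normalized shapes). Merge
#' heights follow the convention height = sqrt(2 * increase in within-
#' cluster sum of squares), under which two singleton classes at Euclidean
#' distance d merge at height d; heights are monotone non-decreasing along
#' any root path. A single class yields an empty merge list.
#'
#' @param classes A [enumerate_classes()] result.
#' @return List of class `"mixture_tree"` with `hclust` (the [stats::hclust]
#'   object, NULL for a single class), `merges` (data.frame child_a,
#'   child_b, height, size; negative children are leaves), `patterns`,
#'   `counts`, `leaf_order` (left-to-right dendrogram order, class
#'   indices).
#' @export
ward_tree <- function(classes) {
  stopifnot(inherits(classes, "mixture_classes"))
  C <- nrow(classes$classes)
  if (C == 1) {
    return(structure(
      list(hclust = NULL,
           merges = data.frame(child_a = integer(), child_b = integer(),
                               height = numeric(), size = integer()),
           patterns = classes$classes$pattern, counts = classes$classes$count,
           leaf_order = 1L),
      class = "mixture_tree"
    ))
  }
  d <- stats::dist(classes$shapes)
  hc <- stats::hclust(d, method = "ward.D2")
  hc$labels <- classes$classes$pattern
  sizes <- integer(C - 1)
  count_of <- function(ch) if (ch < 0) 1L else sizes[ch]
  for (i in seq_len(C - 1)) {
    sizes[i] <- count_of(hc$merge[i, 1]) + count_of(hc$merge[i, 2])
  }
  structure(
    list(hclust = hc,
         merges = data.frame(child_a = hc$merge[, 1], child_b = hc$merge[, 2],
                             height = hc$height, size = sizes),
         patterns = classes$classes$pattern, counts = classes$classes$count,
         leaf_order = hc$order),
    class = "mixture_tree"
  )
}

#' Serialize a mixture tree as Newick
#'
#' Leaf names are the K-bit presence patterns; branch lengths derive from
#' the Ward merge heights.
#'
#' @param tree A [ward_tree()] result with at least 2 leaves.
#' @param file Optional path; if given the Newick string is also written
#'   there.
#' @return Newick string, invisibly if `file` is given.
#' @export
tree_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "mixture_tree"))
  if (is.null(tree$hclust)) stop("a single-class tree has no Newick representation")
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Spectral fingerprint of an ROI
#'
#' The distribution of an ROI's pixels over the leaves of the clustering
#' tree, in left-to-right leaf order: a probability vector summing to 1
#' that characterizes which spectral mixtures a tissue uses. Null-class
#' pixels are excluded.
#'
#' @param roi Logical vector (length N) or integer pixel indices selecting
#'   the ROI's rows of the spectra matrix.
#' @param classes A [enumerate_classes()] result.
#' @param tree The matching [ward_tree()]; supplies the leaf order.
#' @param label Optional ROI label stored on the result.
#' @return Numeric vector of class `"spectral_fingerprint"` (names are leaf
#'   patterns, in leaf order) with attribute `"label"`.
#' @export
fingerprint <- function(roi, classes, tree, label = NULL) {
  stopifnot(inherits(classes, "mixture_classes"), inherits(tree, "mixture_tree"))
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  cls <- classes$assignment[idx]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) stop("ROI contains only null-class pixels; fingerprint undefined")
  counts <- tabulate(cls, nbins = nrow(classes$classes))
  props <- counts[tree$leaf_order] / sum(counts)
  names(props) <- classes$classes$pattern[tree$leaf_order]
  structure(props, class = "spectral_fingerprint", label = label)
}

#' Shannon entropy of a spectral fingerprint
#'
#' `-sum(p * log(p))` over the non-zero leaf proportions; natural log by
#' default (the base is configurable and recorded in run reports). Ranges
#' from 0 (all pixels in one leaf) to log(number of leaves) (uniform).
#'
#' @param fp A [fingerprint()] result or any probability vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return Entropy value.
#' @export
fingerprint_entropy <- function(fp, base = exp(1)) {
  p <- as.numeric(fp)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}
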