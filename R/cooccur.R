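#' Pairwise Sorensen-Dice co-occurrence of spectral components
#'
#' For presence indicator vectors m_j, m_k over pixels,
#' `DSC_jk = 2 (m_j . m_k) / (||m_j||^2 + ||m_k||^2)`, the co-occurrence of
#' two components relative to their total occurrence. High values mean the
#' components usually appear together; low values mean they rarely mix.
#' Pairs where both components never occur are undefined and returned as NA.
#'
#' @param presence A [binarize_presence()] result (or 0/1 matrix).
#' @return K x K symmetric matrix in \[0, 1\] with unit diagonal for any
#'   component that occurs at least once; attribute `"n"` carries the
#'   sample size.
#' @export
dice_matrix <- function(presence) {
  m <- if (inherits(presence, "presence_matrix")) presence$m else as.matrix(presence)
  stopifnot(all(m %in% c(0, 1)))
  storage.mode(m) <- "double"
  cross <- crossprod(m)
  sizes <- diag(cross)             # ||m_j||^2 = occurrence counts
  tot <- outer(sizes, sizes, "+")
  D <- 2 * cross / tot
  D[tot == 0] <- NA_real_
  dimnames(D) <- list(colnames(m), colnames(m))
  attr(D, "n") <- nrow(m)
  D
}

#' Pairwise Pearson correlation of standardized continuous parts
#'
#' Correlates the studentized Box-Cox coefficients of two components over a
#' pixel set chosen by the pairing rule. The default (`"both_present"`)
#' correlates only pixels where both components are present, so the
#' continuous model level is never conflated with the deterministic -3
#' placeholders; `"all_pixels"` uses every pixel (absent entries contribute
#' their -3 values). Pairs with fewer than `min_count` qualifying pixels,
#' or with a degenerate (zero-variance) margin, are flagged undefined (NA)
#' rather than reported.
#'
#' @param std A [standardize_coefficients()] result (or its `std` matrix).
#' @param presence The aligned [binarize_presence()] result.
#' @param pairing `"both_present"` (default) or `"all_pixels"`.
#' @param min_count Minimum number of qualifying pixels per pair.
#' @return K x K symmetric matrix in \[-1, 1\], NA where undefined;
#'   attribute `"counts"` holds the per-pair qualifying pixel counts.
#' @export
pearson_matrix <- function(std, presence,
                           pairing = c("both_present", "all_pixels"),
                           min_count = 10) {
  pairing <- match.arg(pairing)
  X <- if (inherits(std, "standardized_coefficients")) std$std else as.matrix(std)
  m <- if (inherits(presence, "presence_matrix")) presence$m else as.matrix(presence)
  stopifnot(identical(dim(X), dim(m)))
  K <- ncol(X)
  R <- matrix(NA_real_, K, K, dimnames = list(colnames(X), colnames(X)))
  counts <- matrix(0L, K, K, dimnames = dimnames(R))
  for (j in seq_len(K)) {
    for (k in j:K) {
      sel <- if (pairing == "both_present") m[, j] == 1L & m[, k] == 1L else rep(TRUE, nrow(X))
      sel <- sel & !is.na(X[, j]) & !is.na(X[, k])
      nsel <- sum(sel)
      counts[j, k] <- counts[k, j] <- nsel
      if (nsel >= min_count) {
        x <- X[sel, j]; y <- X[sel, k]
        if (stats::sd(x) > 0 && stats::sd(y) > 0) {
          R[j, k] <- R[k, j] <- stats::cor(x, y)
        }
      }
    }
  }
  attr(R, "counts") <- counts
  R
}

#' Nerve-versus-reference contrast of a co-occurrence metric
#'
#' Entrywise difference (nerve minus reference) of two matrices of the same
#' metric; positive entries indicate higher correlation inside the nerve
#' ROIs than in the surrounding reference tissue. Undefined (NA) entries
#' propagate. Swapping the inputs negates the result.
#'
#' @param metric_nerve,metric_reference Conforming K x K metric matrices.
#' @return K x K difference matrix.
#' @export
contrast_difference <- function(metric_nerve, metric_reference) {
  if (!identical(dim(metric_nerve), dim(metric_reference))) {
    stop("metric matrices must have identical shape")
  }
  metric_nerve - metric_reference
}

#' Per-leaf Pearson correlations of shared components
#'
#' Pooled correlations can average away opposite relationships that hold
#' within different mixture classes. This restricts the Pearson analysis to
#' the largest leaves of the clustering tree: it selects the `top_n` leaves
#' by pixel count, intersects their presence patterns to find the
#' components present in every selected leaf, and computes the pairwise
#' correlations of those components within each leaf's pixels.
#'
#' @param std A [standardize_coefficients()] result.
#' @param classes A [enumerate_classes()] result (provides patterns, member
#'   pixels and counts per leaf).
#' @param top_n Number of largest leaves to analyse.
#' @param min_count Minimum pixels per pair passed to [pearson_matrix()].
#' @return List of class `"per_leaf_pcc"` with `leaves` (data.frame:
#'   pattern, count), `components` (shared component indices) and
#'   `pcc` (named list of correlation matrices, one per selected leaf).
#' @export
per_leaf_pcc <- function(std, classes, top_n = 6, min_count = 10) {
  stopifnot(inherits(classes, "mixture_classes"))
  X <- if (inherits(std, "standardized_coefficients")) std$std else as.matrix(std)
  info <- classes$classes
  top_n <- min(top_n, nrow(info))
  sel <- order(info$count, decreasing = TRUE)[seq_len(top_n)]
  pats <- lapply(info$pattern[sel], function(p) {
    as.integer(strsplit(p, "")[[1]])
  })
  shared <- which(Reduce(`&`, lapply(pats, function(b) b == 1L)))
  if (length(shared) == 0) {
    stop(sprintf(
      "the %d largest leaves (%s) share no spectral component",
      top_n, paste(info$pattern[sel], collapse = ", ")
    ))
  }
  pcc <- lapply(sel, function(ci) {
    idx <- classes$members[[ci]]
    Xs <- X[idx, shared, drop = FALSE]
    # all selected components are present in every member pixel, so the
    # both-present pairing is the whole leaf
    ms <- matrix(1L, nrow(Xs), ncol(Xs))
    pearson_matrix(Xs, ms, pairing = "both_present", min_count = min_count)
  })
  names(pcc) <- info$pattern[sel]
  structure(list(leaves = info[sel, , drop = FALSE], components = shared,
                 pcc = pcc),
            class = "per_leaf_pcc")
}
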