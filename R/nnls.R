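#' Constrained linear unmixing against a reference library
#'
#' Classical linear spectral unmixing: each pixel spectrum is decomposed
#' over a fixed library of reference spectra by non-negative least squares,
#' `min ||s - c' H_ref||_2 subject to c >= 0`, solved per pixel with the
#' active-set solver [pracma::lsqnonneg()]. Unlike the data-driven NMF this
#' cannot adapt to depth-dependent spectral coloring, which is what makes it
#' the natural baseline comparator.
#'
#' @param S Non-negative N x L matrix of pixel spectra.
#' @param H_ref K_ref x L matrix of non-negative reference spectra (e.g.
#'   [endmember_library()]).
#' @return N x K_ref matrix of non-negative coefficients (rownames of
#'   `H_ref` become column names).
#' @export
nnls_unmix <- function(S, H_ref) {
  S <- as.matrix(S)
  H_ref <- as.matrix(H_ref)
  stopifnot(ncol(S) == ncol(H_ref))
  if (any(H_ref < 0)) stop("H_ref must be non-negative")
  if (qr(H_ref)$rank < nrow(H_ref)) {
    warning("H_ref is rank deficient; NNLS solutions may be non-unique")
  }
  Ct <- t(H_ref)   # L x K design matrix
  W <- matrix(0, nrow(S), nrow(H_ref))
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    if (all(s == 0)) next
    W[i, ] <- pracma::lsqnonneg(Ct, s)$x
  }
  colnames(W) <- rownames(H_ref)
  W
}
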