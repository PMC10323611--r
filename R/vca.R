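#' Vertex component analysis endmember extraction
#'
#' Implements the classical VCA procedure for hyperspectral unmixing: it
#' assumes the data live (up to noise) in a simplex whose vertices are pure
#' pixels, estimates the signal subspace from an SNR criterion, and then
#' iteratively grows a set of K endmembers by projecting the data onto a
#' direction orthogonal to the subspace already spanned and taking the pixel
#' with extreme projection. Selected endmembers are actual pixel spectra.
#' Non-negative coefficients are then obtained per pixel by constrained
#' least squares ([nnls_unmix()]).
#'
#' With `k = 1` the procedure reduces to picking the pixel with maximal
#' projection onto the first principal direction of the (uncentred) data.
#'
#' @param S Non-negative N x L matrix of pixel spectra, N >= k.
#' @param k Number of endmembers to extract (k <= L).
#' @param seed RNG seed for the random projection directions; the result is
#'   deterministic given the seed.
#' @return List of class `"vca_fit"` with `H` (k x L selected pixel
#'   spectra), `indices` (their row indices in S), `W` (N x k NNLS
#'   coefficients), `snr_db` (estimated SNR), `projective` (whether the
#'   high-SNR projective projection was used).
#' @export
vca_endmembers <- function(S, k, seed = 1L) {
  S <- as.matrix(S)
  N <- nrow(S); L <- ncol(S)
  if (k > L) stop("k must not exceed the number of wavelengths")
  if (N < k) stop("need at least k pixel spectra")
  R <- t(S)                                  # L x N, variables = bands

  if (k == 1) {
    u1 <- svd(R, nu = 1, nv = 0)$u[, 1]
    idx <- which.max(abs(crossprod(R, u1)))
    H <- S[idx, , drop = FALSE]
    W <- nnls_unmix(S, H)
    return(structure(list(H = H, indices = idx, W = W, snr_db = NA_real_,
                          projective = FALSE),
                     class = "vca_fit"))
  }

  r_bar <- rowMeans(R)
  R0 <- R - r_bar
  sv <- svd(R0, nu = min(k, L), nv = 0)
  Ud <- sv$u[, seq_len(min(k, L)), drop = FALSE]
  # SNR estimate from the power captured by the k-dim signal subspace
  p_y <- sum(R^2) / N
  x_p <- crossprod(Ud, R0)                   # k x N scores
  p_x <- sum(x_p^2) / N + sum(r_bar^2)
  snr <- 10 * log10(max((p_x - (k / L) * p_y) / max(p_y - p_x, 1e-300),
                        1e-300))
  snr_th <- 15 + 10 * log10(k)

  if (snr > snr_th) {
    # projective projection onto a k-dim subspace of the raw data
    svr <- svd(R, nu = k, nv = 0)
    Ud <- svr$u[, seq_len(k), drop = FALSE]
    x <- crossprod(Ud, R)                    # k x N
    u <- rowMeans(x)
    denom <- colSums(x * u)
    denom[abs(denom) < 1e-300] <- 1e-300
    y <- sweep(x, 2, denom, "/")
    projective <- TRUE
  } else {
    d <- k - 1
    Ud <- sv$u[, seq_len(d), drop = FALSE]
    x <- crossprod(Ud, R0)                   # d x N
    c_max <- sqrt(max(colSums(x^2)))
    y <- rbind(x, c_max)
    projective <- FALSE
  }

  indices <- integer(k)
  A <- matrix(0, k, k)
  A[k, 1] <- 1
  with_seed(seed, {
    for (i in seq_len(k)) {
      w <- stats::runif(k)
      f <- (diag(k) - A %*% pracma::pinv(A)) %*% w
      nf <- sqrt(sum(f^2))
      if (nf < 1e-300) f <- w else f <- f / nf
      v <- crossprod(y, f)
      indices[i] <- which.max(abs(v))
      A[, i] <- y[, indices[i]]
    }
  })

  H <- S[indices, , drop = FALSE]
  W <- nnls_unmix(S, H)
  structure(list(H = H, indices = indices, W = W, snr_db = snr,
                 projective = projective),
            class = "vca_fit")
}
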