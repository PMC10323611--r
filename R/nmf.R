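#' Parameters for regularized non-negative matrix factorization
#'
#' The unmixing solves, over entrywise non-negative W (N x K coefficients)
#' and H (K x L component spectra),
#'
#'   minimize  1/2 ||S - W H||_F^2
#'             + lambda1 (||W||_1 + ||H||_1)
#'             + 1/2 lambdaF (||W||_F^2 + ||H||_F^2)
#'
#' where ||.||_1 is the entrywise L1 norm. The strong L1 term promotes a
#' maximally sparse decomposition (tissue spectra are mixtures of few
#' dominant chromophores); the Frobenius term keeps the factors bounded.
#' The defaults K = 9, lambda1 = 80, lambdaF = 20 are the operating point
#' used for in vivo nerve datasets.
#'
#' @param k Number of spectral components.
#' @param lambda1 Entrywise L1 penalty weight (>= 0).
#' @param lambda_f Frobenius (L2) penalty weight (>= 0).
#' @param max_iter Maximum outer iterations (one sweep over W and H each).
#' @param tol Relative objective-decrease tolerance for convergence.
#' @param init `"nndsvd"` (deterministic, SVD-based) or `"random"`.
#' @param seed RNG seed, used by `init = "random"`.
#' @param eps_zero Relative threshold below which converged coefficients are
#'   snapped to exact 0 (fraction of the per-component maximum), so that the
#'   downstream zero/non-zero dichotomy is well defined.
#' @return List of class `"nmf_params"`.
#' @export
nmf_params <- function(k = 9, lambda1 = 80, lambda_f = 20, max_iter = 500,
                       tol = 1e-9, init = c("nndsvd", "random"), seed = NULL,
                       eps_zero = 1e-9) {
  init <- match.arg(init)
  stopifnot(k >= 1, lambda1 >= 0, lambda_f >= 0, max_iter >= 1, tol >= 0,
            eps_zero >= 0)
  structure(list(k = as.integer(k), lambda1 = lambda1, lambda_f = lambda_f,
                 max_iter = as.integer(max_iter), tol = tol, init = init,
                 seed = seed, eps_zero = eps_zero),
            class = "nmf_params")
}

# Exact value of the regularized objective.
nmf_objective <- function(S, W, H, lambda1, lambda_f) {
  R <- S - W %*% H
  0.5 * sum(R * R) + lambda1 * (sum(W) + sum(H)) +
    0.5 * lambda_f * (sum(W * W) + sum(H * H))
}

# NNDSVD initialization (deterministic). Zero entries are backfilled with a
# small positive constant ("nndsvda" variant) so no component starts locked.
nndsvd_init <- function(S, k) {
  sv <- svd(S, nu = k, nv = k)
  W <- matrix(0, nrow(S), k)
  H <- matrix(0, k, ncol(S))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        s <- sqrt(sv$d[j] * npos)
        W[, j] <- s * up / sqrt(sum(up^2))
        H[j, ] <- s * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        s <- sqrt(sv$d[j] * nneg)
        W[, j] <- s * un / sqrt(sum(un^2))
        H[j, ] <- s * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(S) / 100
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

#' Regularized NMF spectral unmixing
#'
#' Factorizes a non-negative pixel-spectra matrix into K non-negative
#' spectral components and coefficients by block coordinate descent on the
#' regularized objective of [nmf_params()]. Each update minimizes the exact
#' objective over one column of W (or row of H) with everything else fixed
#' (closed-form soft-thresholded non-negative ridge update), so the recorded
#' objective trace is non-increasing. After convergence, coefficients at or
#' below `eps_zero` times their component maximum are snapped to exact zero
#' and components are reordered by descending total coefficient mass.
#'
#' @param S Non-negative N x L matrix of pixel spectra (see
#'   [spectra_matrix()]); must not be all zero.
#' @param params An [nmf_params()] object.
#' @return List of class `"nmf_fit"` with `W` (N x K), `H` (K x L),
#'   `objective` (exact objective per outer iteration, non-increasing),
#'   `relative_error` (see [relative_error()]), `component_order` (the
#'   permutation applied), `iterations`, `params`.
#' @export
nmf_unmix <- function(S, params = nmf_params()) {
  stopifnot(inherits(params, "nmf_params"))
  S <- as.matrix(S)
  if (any(S < 0)) stop("S must be entrywise non-negative")
  if (all(S == 0)) stop("S is all zero: factorization is degenerate")
  n <- nrow(S); L <- ncol(S); k <- params$k
  l1 <- params$lambda1; lf <- params$lambda_f

  fac <- if (params$init == "nndsvd") {
    nndsvd_init(S, k)
  } else {
    with_seed(params$seed, {
      sc <- sqrt(mean(S) / k)
      list(W = matrix(abs(stats::rnorm(n * k, sd = sc)), n, k),
           H = matrix(abs(stats::rnorm(k * L, sd = sc)), k, L))
    })
  }
  W <- fac$W; H <- fac$H

  obj <- numeric(params$max_iter + 1)
  obj[1] <- nmf_objective(S, W, H, l1, lf)
  it <- 0
  for (iter in seq_len(params$max_iter)) {
    # update W columns (fix H)
    HHt <- tcrossprod(H)                    # k x k
    SHt <- tcrossprod(S, H)                 # n x k
    for (j in seq_len(k)) {
      denom <- HHt[j, j] + lf
      if (denom <= 0) { W[, j] <- 0; next }
      g <- SHt[, j] - W %*% HHt[, j] + W[, j] * HHt[j, j]
      W[, j] <- pmax(0, (g - l1) / denom)
    }
    # update H rows (fix W)
    WtW <- crossprod(W)                     # k x k
    WtS <- crossprod(W, S)                  # k x L
    for (j in seq_len(k)) {
      denom <- WtW[j, j] + lf
      if (denom <= 0) { H[j, ] <- 0; next }
      g <- WtS[j, ] - WtW[j, ] %*% H + WtW[j, j] * H[j, ]
      H[j, ] <- pmax(0, (g - l1) / denom)
    }
    it <- iter
    obj[iter + 1] <- nmf_objective(S, W, H, l1, lf)
    if (obj[iter] - obj[iter + 1] <= params$tol * max(obj[iter], 1e-300)) break
  }
  obj <- obj[seq_len(it + 1)]

  # snap near-zero coefficients to exact zero (per-component threshold)
  cmax <- apply(W, 2, max)
  thr <- params$eps_zero * cmax
  W <- sweep(W, 2, thr, function(x, t) ifelse(x <= t, 0, x))

  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("comp", seq_len(k))
  if (!is.null(colnames(S))) colnames(H) <- colnames(S)

  structure(
    list(W = W, H = H, objective = obj,
         relative_error = relative_error(S, W, H),
         component_order = ord, iterations = it, params = params),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "regularized NMF fit: %d x %d spectra, K = %d, %d iterations, relative error %.4g%%\n",
    nrow(x$W), ncol(x$H), ncol(x$W), x$iterations, 100 * x$relative_error
  ))
  invisible(x)
}

#' Relative reconstruction error of a factorization
#'
#' The squared-Frobenius quotient `||S - W H||_F^2 / ||S||_F^2`, the
#' goodness-of-fit measure used to compare unmixing methods (reported as a
#' percentage in run reports).
#'
#' @param S Data matrix.
#' @param W,H Factor matrices with conforming shapes.
#' @return Non-negative scalar (0 for a perfect reconstruction, 1 for W = 0).
#' @export
relative_error <- function(S, W, H) {
  S <- as.matrix(S)
  den <- sum(S * S)
  if (den == 0) stop("||S||_F is zero: relative error undefined")
  R <- S - W %*% H
  sum(R * R) / den
}

#' Match estimated components to reference spectra by cosine similarity
#'
#' Solutions of NMF-type factorizations are defined up to row permutation
#' and positive scaling of H, so recovery is assessed after greedy maximal
#' cosine-similarity assignment of estimated to reference rows.
#'
#' @param H_est,H_ref Matrices with the same number of columns.
#' @return List with `assignment` (for each reference row, the matched
#'   estimated row) and `cosine` (the matched similarities).
#' @export
match_components <- function(H_est, H_ref) {
  stopifnot(ncol(H_est) == ncol(H_ref))
  normr <- function(M) {
    n <- sqrt(rowSums(M^2))
    M / pmax(n, 1e-300)
  }
  C <- normr(H_ref) %*% t(normr(H_est))  # ref x est cosine
  nref <- nrow(H_ref)
  assignment <- integer(nref)
  cosine <- numeric(nref)
  Cw <- C
  for (step in seq_len(min(nref, nrow(H_est)))) {
    ij <- arrayInd(which.max(Cw), dim(Cw))
    assignment[ij[1]] <- ij[2]
    cosine[ij[1]] <- C[ij[1], ij[2]]
    Cw[ij[1], ] <- -Inf
    Cw[, ij[2]] <- -Inf
  }
  list(assignment = assignment, cosine = cosine)
}
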