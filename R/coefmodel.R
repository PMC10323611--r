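#' Binarize unmixing coefficients into presence indicators
#'
#' The sparse unmixing coefficients are modelled per component as a
#' two-part (zero-inflated) mixture: a Bernoulli indicator of whether the
#' component is present at a pixel, and a continuous law for the non-zero
#' part. This function extracts the Bernoulli level: `m_ij = 1` iff
#' `w_ij > eps_zero * max_i(w_ij)` (the same relative-zero convention used
#' when snapping converged NMF coefficients).
#'
#' @param W Non-negative N x K coefficient matrix.
#' @param eps_zero Relative zero threshold (fraction of each component's
#'   maximum coefficient).
#' @return List of class `"presence_matrix"` with `m` (0/1 integer matrix)
#'   and `p` (per-component presence rates, the Bernoulli parameters).
#' @export
binarize_presence <- function(W, eps_zero = 1e-9) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be non-negative")
  thr <- eps_zero * apply(W, 2, max)
  m <- 1L * sweep(W, 2, thr, ">")
  colnames(m) <- colnames(W)
  structure(list(m = m, p = colMeans(m), eps_zero = eps_zero),
            class = "presence_matrix")
}

#' Box-Cox power transform
#'
#' `(x^beta - 1) / beta` for `beta != 0`, `log(x)` for `beta = 0`; strictly
#' increasing in `x` for any `beta`, so ranks are preserved.
#'
#' @param x Positive values.
#' @param beta Power parameter.
#' @return Transformed values.
#' @export
boxcox_transform <- function(x, beta) {
  if (abs(beta) < 1e-12) log(x) else (x^beta - 1) / beta
}

# Profile log-likelihood of the Box-Cox Gaussian model (including the
# Jacobian term), up to constants.
boxcox_loglik <- function(x, beta) {
  y <- boxcox_transform(x, beta)
  n <- length(x)
  s2 <- mean((y - mean(y))^2)
  -n / 2 * log(s2) + (beta - 1) * sum(log(x))
}

#' Maximum-likelihood Box-Cox power fit
#'
#' Fits the power parameter of the Box-Cox transform by maximizing the
#' Gaussian profile log-likelihood (with Jacobian term) over beta in
#' \[-5, 5\]: a coarse grid locates the mode, then golden-section/parabolic
#' refinement ([stats::optimize()]) polishes it to tolerance 1e-4. The
#' transform symmetrizes the strongly right-skewed non-zero coefficient
#' distributions and acts as a partial fluence (depth) adjustment.
#'
#' @param x Positive values with at least 3 distinct entries.
#' @param interval Search interval for beta.
#' @return List with `beta` (the MLE), `transformed` (the transformed
#'   values), `loglik` (the profile log-likelihood at the optimum).
#' @export
fit_boxcox <- function(x, interval = c(-5, 5)) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0)) stop("Box-Cox requires strictly positive finite values")
  if (length(unique(x)) < 3) stop("Box-Cox fit requires at least 3 distinct values")
  grid <- seq(interval[1], interval[2], length.out = 51)
  ll <- vapply(grid, function(b) boxcox_loglik(x, b), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(b) boxcox_loglik(x, b),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
  beta <- opt$maximum
  list(beta = beta, transformed = boxcox_transform(x, beta),
       loglik = opt$objective)
}

#' Standardize unmixing coefficients via the two-part mixture model
#'
#' Per fitting scope (e.g. nerve class) and component, the non-zero
#' coefficients are Box-Cox transformed ([fit_boxcox()]) and studentized to
#' zero mean and unit standard deviation; absent entries are set to exactly
#' -3, the 3-sigma convention that keeps the deterministic zero part just
#' below the bulk of a standard normal. The result makes components whose
#' raw signal differs by orders of magnitude directly comparable.
#'
#' Cells (scope x component) whose non-zero part has fewer than 3 distinct
#' values cannot support a Box-Cox fit; they are flagged unusable (their
#' standardized entries are NA), never silently dropped.
#'
#' @param W Non-negative N x K coefficient matrix.
#' @param presence A [binarize_presence()] result aligned with `W`.
#' @param scope Optional factor of length N partitioning the pixels into
#'   independent fitting scopes (default: a single scope).
#' @return List of class `"standardized_coefficients"` with:
#'   `std` (N x K matrix: studentized Box-Cox values where present, exactly
#'   -3 where absent, NA in unusable cells) and `models` (data.frame with
#'   one row per scope x component: `scope`, `component`, `p`, `beta`,
#'   `mean`, `sd` of the transformed non-zero part, `n_present`, `usable`).
#' @export
standardize_coefficients <- function(W, presence, scope = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  W <- as.matrix(W)
  m <- presence$m
  stopifnot(identical(dim(W), dim(m)))
  n <- nrow(W); K <- ncol(W)
  if (is.null(scope)) scope <- factor(rep("all", n))
  scope <- as.factor(scope)
  stopifnot(length(scope) == n)

  std <- matrix(-3, n, K)
  colnames(std) <- colnames(W)
  models <- list()
  for (sc in levels(scope)) {
    in_sc <- scope == sc
    for (j in seq_len(K)) {
      present <- in_sc & m[, j] == 1L
      vals <- W[present, j]
      np <- sum(present)
      if (length(unique(vals)) >= 3) {
        fit <- fit_boxcox(vals)
        mu <- mean(fit$transformed)
        sd_j <- stats::sd(fit$transformed)
        std[present, j] <- (fit$transformed - mu) / sd_j
        models[[length(models) + 1]] <- data.frame(
          scope = sc, component = colnames(W)[j] %||% j,
          p = mean(m[in_sc, j]), beta = fit$beta, mean = mu, sd = sd_j,
          n_present = np, usable = TRUE
        )
      } else {
        std[in_sc, j] <- NA_real_
        models[[length(models) + 1]] <- data.frame(
          scope = sc, component = colnames(W)[j] %||% j,
          p = mean(m[in_sc, j]), beta = NA_real_, mean = NA_real_,
          sd = NA_real_, n_present = np, usable = FALSE
        )
      }
    }
  }
  structure(list(std = std, models = do.call(rbind, models), scope = scope),
            class = "standardized_coefficients")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
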