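# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity from its definition (double loops, dense grids,
# generic optimizers) and never call the package's fast paths.

# Sorensen-Dice of presence columns, straight from the definition.
naive_dice <- function(m) {
  K <- ncol(m)
  D <- matrix(NA_real_, K, K)
  for (j in 1:K) {
    for (k in 1:K) {
      num <- 2 * sum(m[, j] * m[, k])
      den <- sum(m[, j]^2) + sum(m[, k]^2)
      if (den > 0) D[j, k] <- num / den
    }
  }
  D
}

# Pearson correlation over the both-present set, from the covariance quotient.
naive_pearson <- function(X, m, min_count = 1) {
  K <- ncol(X)
  R <- matrix(NA_real_, K, K)
  for (j in 1:K) {
    for (k in 1:K) {
      sel <- m[, j] == 1 & m[, k] == 1
      if (sum(sel) < min_count) next
      x <- X[sel, j]; y <- X[sel, k]
      sx <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
      sy <- sqrt(sum((y - mean(y))^2) / (length(y) - 1))
      if (sx == 0 || sy == 0) next
      R[j, k] <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
    }
  }
  R
}

# Box-Cox power MLE by dense grid search over the profile log-likelihood.
boxcox_grid_oracle <- function(x, grid = seq(-5, 5, by = 0.001)) {
  ll <- vapply(grid, function(b) {
    y <- if (abs(b) < 1e-12) log(x) else (x^b - 1) / b
    -length(x) / 2 * log(mean((y - mean(y))^2)) + (b - 1) * sum(log(x))
  }, numeric(1))
  grid[which.max(ll)]
}

# Brute-force Ward agglomeration over raw points: at each step evaluates the
# increase in within-cluster sum of squares for every candidate merge and
# takes the smallest; heights use the sqrt(2 * delta-SSE) convention.
ward_brute <- function(shapes) {
  clusters <- lapply(seq_len(nrow(shapes)), function(i) shapes[i, , drop = FALSE])
  sse <- function(pts) sum(sweep(pts, 2, colMeans(pts))^2)
  heights <- numeric(0)
  merges <- list()
  ids <- as.list(seq_len(nrow(shapes)))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d_sse <- sse(rbind(clusters[[a]], clusters[[b]])) -
          sse(clusters[[a]]) - sse(clusters[[b]])
        if (d_sse < best[1]) best <- c(d_sse, a, b)
      }
    }
    a <- best[2]; b <- best[3]
    heights <- c(heights, sqrt(2 * best[1]))
    merges[[length(merges) + 1]] <- sort(c(unlist(ids[[a]]), unlist(ids[[b]])))
    clusters[[a]] <- rbind(clusters[[a]], clusters[[b]])
    ids[[a]] <- c(ids[[a]], ids[[b]])
    clusters[[b]] <- NULL
    ids[[b]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Generic-optimizer oracle for the regularized NMF objective on tiny
# problems: multi-start box-constrained quasi-Newton over the stacked
# (W, H) parameters, minimizing the exact objective.
nmf_optim_oracle <- function(S, k, lambda1, lambda_f, n_starts = 30, seed = 99) {
  n <- nrow(S); L <- ncol(S)
  obj <- function(theta) {
    W <- matrix(theta[seq_len(n * k)], n, k)
    H <- matrix(theta[-seq_len(n * k)], k, L)
    R <- S - W %*% H
    0.5 * sum(R * R) + lambda1 * (sum(W) + sum(H)) +
      0.5 * lambda_f * (sum(W * W) + sum(H * H))
  }
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    theta0 <- abs(rnorm(n * k + k * L, sd = sqrt(mean(S) / k) + 0.1))
    fit <- optim(theta0, obj, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = 2000, factr = 1e4))
    best <- min(best, fit$value)
  }
  best
}

# Small phantom geometry used to keep end-to-end tests fast; structures are
# placed relative to the field of view so any image size stays valid.
small_layout <- function(nrow = 80, ncol = 80) {
  px <- 0.1
  fov_ax <- nrow * px
  fov_lat <- ncol * px
  nerve_ax <- 0.55 * fov_ax
  nerve_lat <- 0.45 * fov_lat
  r_lat <- 0.17 * fov_lat
  r_ax <- 0.11 * fov_ax
  phantom_layout(
    nrow = nrow, ncol = ncol, pixel_mm = px,
    layer_depths_mm = c(epidermis = 0.05 * fov_ax, dermis = 0.15 * fov_ax,
                        fat = 0.3 * fov_ax),
    nerve = list(
      center_mm = c(lateral = nerve_lat, axial = nerve_ax),
      radii_mm = c(lateral = r_lat, axial = r_ax),
      fascicles = data.frame(
        lateral_mm = nerve_lat + c(-0.4, 0.4) * r_lat,
        axial_mm = nerve_ax + c(-0.2, 0.3) * r_ax,
        radius_mm = rep(0.25 * r_ax, 2)
      )
    ),
    vessels = data.frame(
      lateral_mm = c(0.8, 0.25) * fov_lat,
      axial_mm = c(0.52, 0.09) * fov_ax,
      radius_mm = c(0.05, 0.03) * fov_ax,
      so2 = c(0.95, 0.6)
    )
  )
}
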