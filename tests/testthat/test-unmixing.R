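test_that("relative error matches hand evaluations of the Frobenius quotient", {
  S <- diag(2)
  W <- matrix(c(1, 0), 2, 1)
  H <- matrix(c(1, 0), 1, 2)
  expect_equal(relative_error(S, W, H), 0.5)          # reconstructs [[1,0],[0,0]]
  expect_equal(relative_error(S, cbind(c(1, 0), c(0, 1)), diag(2)), 0)
  expect_equal(relative_error(S, matrix(0, 2, 2), diag(2)), 1)
  expect_error(relative_error(matrix(0, 2, 2), W, H), "undefined")
})

test_that("an exact factorization is recovered when one exists", {
  E <- endmember_library()
  set.seed(11)
  W0 <- matrix(0, 400, nrow(E))
  for (i in seq_len(nrow(W0))) {
    idx <- sample(nrow(E), sample(1:2, 1))
    W0[i, idx] <- runif(length(idx), 0.2, 2)
  }
  S <- W0 %*% E
  fit <- nmf_unmix(S, nmf_params(k = nrow(E), lambda1 = 0, lambda_f = 0,
                                 max_iter = 2000, tol = 1e-14))
  expect_lt(fit$relative_error, 1e-6)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
})

test_that("rank-1 data yield the true spectrum at K = 1", {
  E <- endmember_library()
  s <- E["lipid", ]
  S <- outer(seq(0.5, 5, length.out = 60), s)   # positive scalings of one spectrum
  fit <- nmf_unmix(S, nmf_params(k = 1, lambda1 = 0, lambda_f = 0,
                                 max_iter = 500, tol = 1e-14))
  cossim <- sum(fit$H[1, ] * s) / sqrt(sum(fit$H[1, ]^2) * sum(s^2))
  expect_gt(cossim, 0.999)
})

test_that("the solver attains the brute-force optimum on a tiny L1 problem", {
  set.seed(5)
  S <- matrix(runif(24, 0, 2), 6, 4)
  l1 <- 2; lf <- 1
  fit <- nmf_unmix(S, nmf_params(k = 2, lambda1 = l1, lambda_f = lf,
                                 max_iter = 5000, tol = 1e-15))
  ours <- fit$objective[length(fit$objective)]
  oracle <- nmf_optim_oracle(S, 2, l1, lf)
  expect_lt(abs(ours - oracle) / oracle, 1e-4)
})

test_that("the exact regularized objective never increases along iterations", {
  set.seed(21)
  S <- matrix(runif(600, 0, 3), 60, 10)
  for (par in list(nmf_params(k = 3, lambda1 = 0, lambda_f = 0, max_iter = 80),
                   nmf_params(k = 3, lambda1 = 5, lambda_f = 2, max_iter = 80),
                   nmf_params(k = 4, lambda1 = 50, lambda_f = 10, max_iter = 80,
                              init = "random", seed = 2))) {
    fit <- nmf_unmix(S, par)
    expect_true(all(diff(fit$objective) <= 1e-10 * abs(fit$objective[1])))
  }
})

test_that("degenerate spectra matrices are rejected", {
  expect_error(nmf_unmix(matrix(-1, 2, 2)), "non-negative")
  expect_error(nmf_unmix(matrix(0, 3, 3)), "all zero")
})

test_that("components come back ordered by total coefficient mass", {
  set.seed(31)
  S <- matrix(runif(800, 0, 2), 80, 10)
  fit <- nmf_unmix(S, nmf_params(k = 4, lambda1 = 1, lambda_f = 1, max_iter = 100))
  expect_true(all(diff(colSums(fit$W)) <= 1e-12))
})

test_that("NNLS unmixing solves each pixel's constrained least squares", {
  E <- endmember_library()
  # exact member of the cone
  S <- rbind(2 * E[3, ], rep(0, ncol(E)))
  W <- nnls_unmix(S, E)
  expect_equal(as.numeric(W[1, ]), c(0, 0, 2, 0, 0, 0), tolerance = 1e-8)
  expect_equal(as.numeric(W[2, ]), rep(0, 6))
})

test_that("NNLS matches the active-set hand solution outside the cone", {
  H <- rbind(a = c(1, 0), b = c(1, 1))
  s <- c(-0.5, 2)  # outside the non-negative cone of the rows
  W <- nnls_unmix(matrix(s, 1, 2), H)
  # brute force over active sets of the 2-endmember problem
  cands <- list(c(0, 0))
  c_a <- max(0, sum(s * H[1, ]) / sum(H[1, ]^2))
  c_b <- max(0, sum(s * H[2, ]) / sum(H[2, ]^2))
  cands <- c(cands, list(c(c_a, 0), c(0, c_b)))
  full <- tryCatch(solve(H %*% t(H), H %*% s), error = function(e) NULL)
  if (!is.null(full) && all(full >= 0)) cands <- c(cands, list(as.numeric(full)))
  errs <- vapply(cands, function(cc) sum((s - cc %*% H)^2), numeric(1))
  best <- cands[[which.min(errs)]]
  expect_equal(as.numeric(W), best, tolerance = 1e-8)
})

test_that("rank-deficient reference libraries trigger a warning, not failure", {
  H <- rbind(c(1, 2, 3), c(2, 4, 6))
  expect_warning(W <- nnls_unmix(matrix(c(1, 2, 3), 1, 3), H), "rank deficient")
  expect_true(all(W >= 0))
})

test_that("VCA recovers simplex vertices from pure-pixel data", {
  E <- endmember_library()
  K <- nrow(E)
  set.seed(13)
  n <- 300
  W0 <- matrix(0, n, K)
  for (i in seq_len(n)) {
    a <- rgamma(K, 0.4)
    W0[i, ] <- a / sum(a)
  }
  W0[1:K, ] <- diag(K)  # pure pixels at the vertices
  S <- W0 %*% E
  v <- vca_endmembers(S, K, seed = 4)
  mt <- match_components(v$H, E)
  expect_true(all(mt$cosine > 0.99))
  expect_true(all(v$W >= 0))
})

test_that("VCA with K = 1 picks the extreme pixel on the first principal axis", {
  set.seed(17)
  S <- matrix(runif(200, 0.1, 2), 50, 4)
  v <- vca_endmembers(S, 1, seed = 1)
  u1 <- svd(t(S), nu = 1, nv = 0)$u[, 1]
  expect_identical(as.integer(v$indices), as.integer(which.max(abs(S %*% u1))))
})

test_that("the recovered VCA endmember set is invariant to pixel order", {
  E <- endmember_library()
  set.seed(19)
  W0 <- matrix(rgamma(120 * 6, 0.5), 120, 6)
  W0[1:6, ] <- diag(6) * 1.5
  S <- W0 %*% E
  v1 <- vca_endmembers(S, 3, seed = 5)
  perm <- sample(nrow(S))
  v2 <- vca_endmembers(S[perm, ], 3, seed = 5)
  sortrows <- function(M) M[do.call(order, as.data.frame(M)), ]
  expect_equal(sortrows(v1$H), sortrows(v2$H), ignore_attr = TRUE)
})

test_that("VCA rejects more endmembers than wavelengths", {
  expect_error(vca_endmembers(matrix(1, 10, 3), 4), "exceed")
})
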