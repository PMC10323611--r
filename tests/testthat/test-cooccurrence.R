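test_that("Dice co-occurrence matches hand evaluations", {
  m <- cbind(j = c(1, 1, 0, 1), k = c(1, 0, 0, 1), l = c(0, 0, 1, 0),
             z = c(0, 0, 0, 0))
  D <- dice_matrix(m)
  expect_equal(D["j", "k"], 0.8)            # 2*2 / (3+2)
  expect_equal(D["j", "j"], 1)              # identical non-zero columns
  expect_equal(D["j", "l"], 0)              # disjoint support
  expect_true(is.na(D["z", "z"]))           # never-occurring pair undefined
  expect_equal(D, t(D))
  expect_identical(attr(D, "n"), 4L)
})

test_that("Pearson co-occurrence matches hand evaluations", {
  X <- cbind(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  m <- matrix(1L, 4, 2)
  R <- pearson_matrix(X, m, min_count = 2)
  expect_equal(R[1, 2], 0.6)
  expect_equal(unname(diag(R)), c(1, 1))

  R2 <- pearson_matrix(cbind(X[, 1], -X[, 1]), m, min_count = 2)
  expect_equal(R2[1, 2], -1)

  # pairs below the minimum co-occurrence count are flagged, not reported
  R3 <- pearson_matrix(X, m, min_count = 10)
  expect_true(all(is.na(R3)))
})

test_that("both metrics agree with naive double-loop references", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    K <- sample(2:5, 1)
    m <- matrix(rbinom(n * K, 1, 0.6), n, K)
    X <- matrix(rnorm(n * K), n, K)
    D <- dice_matrix(m)
    expect_equal(unclass(D), naive_dice(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
    R <- pearson_matrix(X, m, min_count = 3)
    expect_equal(unclass(R), naive_pearson(X, m, min_count = 3),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("nerve-minus-reference differences behave antisymmetrically", {
  A <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  B <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(contrast_difference(A, A), matrix(0, 2, 2))
  expect_equal(contrast_difference(A, B), -contrast_difference(B, A))
  expect_equal(contrast_difference(A, B)[1, 2], 0.5)
  B[1, 2] <- NA
  expect_true(is.na(contrast_difference(A, B)[1, 2]))
  expect_error(contrast_difference(A, matrix(0, 3, 3)), "shape")
})

test_that("a single leaf containing all pixels reduces to the global PCC", {
  set.seed(8)
  n <- 200
  W <- cbind(exp(rnorm(n)), exp(rnorm(n)), 0)
  colnames(W) <- c("c1", "c2", "c3")
  pr <- binarize_presence(W)
  st <- standardize_coefficients(W, pr)
  cls <- enumerate_classes(pr, W %*% matrix(runif(12, 0.5, 1), 3, 4))
  expect_identical(nrow(cls$classes), 1L)
  res <- per_leaf_pcc(st, cls, top_n = 1)
  expect_identical(res$components, c(1L, 2L))
  glob <- pearson_matrix(st$std[, 1:2], pr$m[, 1:2], min_count = 10)
  expect_equal(unclass(res$pcc[[1]]), unclass(glob), ignore_attr = TRUE)
})

test_that("leaves sharing no component raise a named error", {
  W <- rbind(cbind(runif(30, 1, 2), 0), cbind(0, runif(30, 1, 2)))
  colnames(W) <- c("a", "b")
  pr <- binarize_presence(W)
  st <- standardize_coefficients(W, pr)
  cls <- enumerate_classes(pr, W %*% matrix(runif(8, 0.5, 1), 2, 4))
  expect_error(per_leaf_pcc(st, cls, top_n = 2), "share no spectral component")
})

test_that("per-leaf correlations undo the pooled averaging effect", {
  # two mixture classes share components 1 and 2; their continuous parts are
  # positively coupled in one class and negatively in the other, so the
  # pooled correlation shrinks toward zero while per-leaf values keep sign
  set.seed(15)
  n <- 600
  z <- rnorm(n)
  make_vals <- function(rho) {
    x <- z + rnorm(n, sd = 0.3)
    y <- rho * z + rnorm(n, sd = sqrt(1 - rho^2)) * 1
    cbind(exp(x), exp(y))
  }
  A <- cbind(make_vals(0.85), 0)              # pattern 110
  B <- cbind(make_vals(-0.85), runif(n, 1, 2))  # pattern 111
  W <- rbind(A, B)
  colnames(W) <- c("c1", "c2", "c3")
  pr <- binarize_presence(W)
  scope <- factor(rep(c("A", "B"), each = n))
  st <- standardize_coefficients(W, pr, scope = scope)
  cls <- enumerate_classes(pr, W %*% matrix(runif(12, 0.5, 1.5), 3, 4))
  res <- per_leaf_pcc(st, cls, top_n = 2)

  rho_by_leaf <- vapply(res$pcc, function(M) M[1, 2], numeric(1))
  rho_A <- rho_by_leaf[["110"]]
  rho_B <- rho_by_leaf[["111"]]
  expect_gt(rho_A, 0.3)
  expect_lt(rho_B, -0.3)

  pooled <- pearson_matrix(st, pr, min_count = 10)[1, 2]
  expect_lt(abs(pooled), min(abs(rho_A), abs(rho_B)))
})
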