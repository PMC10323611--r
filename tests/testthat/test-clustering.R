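make_presence <- function(m) {
  structure(list(m = m, p = colMeans(m), eps_zero = 1e-9),
            class = "presence_matrix")
}

test_that("mixture classes enumerate distinct observed presence patterns", {
  m <- rbind(matrix(rep(c(1L, 0L, 1L), 30), 30, 3, byrow = TRUE),
             matrix(rep(c(0L, 1L, 1L), 70), 70, 3, byrow = TRUE),
             matrix(0L, 5, 3))
  S <- matrix(runif(105 * 4, 0.5, 2), 105, 4)
  cls <- enumerate_classes(make_presence(m), S)
  expect_identical(nrow(cls$classes), 2L)
  expect_identical(sort(cls$classes$count), c(30L, 70L))
  expect_identical(cls$null_count, 5L)
  expect_true(all(is.na(cls$assignment[101:105])))
  expect_lte(nrow(cls$classes), 2^cls$k)

  one <- enumerate_classes(make_presence(matrix(1L, 10, 3)),
                           matrix(runif(40, 1, 2), 10, 4))
  expect_identical(nrow(one$classes), 1L)
})

test_that("class mean shapes are averages of unit-normalized members", {
  expect_equal(as.numeric(class_mean_shape(matrix(c(3, 4), 1, 2))), c(0.6, 0.8))
  two <- class_mean_shape(rbind(c(3, 4), c(6, 8)))
  expect_equal(as.numeric(two), c(0.6, 0.8))
  mix <- class_mean_shape(rbind(c(1, 0), c(0, 1)))
  expect_equal(as.numeric(mix), c(0.5, 0.5))
  expect_equal(sqrt(sum(mix^2)), sqrt(2) / 2)
  dropped <- class_mean_shape(rbind(c(0, 0), c(3, 4)))
  expect_identical(attr(dropped, "dropped"), 1L)
  expect_error(class_mean_shape(matrix(0, 2, 2)), "zero norm")
})

test_that("Ward merges follow the minimum-variance criterion", {
  # two classes at Euclidean distance d merge at height d
  mk_classes <- function(shapes) {
    structure(
      list(classes = data.frame(pattern = sprintf("p%d", seq_len(nrow(shapes))),
                                count = rep(1L, nrow(shapes))),
           shapes = shapes,
           members = as.list(seq_len(nrow(shapes))),
           assignment = seq_len(nrow(shapes)),
           null_count = 0L, k = 2L),
      class = "mixture_classes"
    )
  }
  d <- 3.7
  tr <- ward_tree(mk_classes(rbind(c(0, 0), c(d, 0))))
  expect_equal(tr$merges$height, d)

  # 1D shapes 0, 1, 10: the first merge joins {0, 1}
  tr3 <- ward_tree(mk_classes(matrix(c(0, 1, 10), 3, 1)))
  expect_setequal(as.integer(tr3$merges[1, c("child_a", "child_b")]),
                  c(-1L, -2L))

  # duplicated shapes merge at height 0
  trd <- ward_tree(mk_classes(rbind(c(1, 1), c(1, 1), c(5, 5))))
  expect_equal(trd$merges$height[1], 0)

  # single class: empty merge list
  tr1 <- ward_tree(mk_classes(matrix(c(2, 2), 1, 2)))
  expect_identical(nrow(tr1$merges), 0L)
})

test_that("Ward heights match a brute-force oracle on small class sets", {
  set.seed(23)
  for (rep in 1:10) {
    C <- sample(2:4, 1)
    shapes <- matrix(rnorm(C * 3), C, 3)
    cls <- structure(
      list(classes = data.frame(pattern = sprintf("p%d", 1:C),
                                count = rep(1L, C)),
           shapes = shapes, members = as.list(1:C), assignment = 1:C,
           null_count = 0L, k = 3L),
      class = "mixture_classes"
    )
    tr <- ward_tree(cls)
    oracle <- ward_brute(shapes)
    expect_equal(tr$merges$height, oracle$heights, tolerance = 1e-10)
    # heights monotone non-decreasing along the merge sequence
    expect_true(all(diff(tr$merges$height) >= -1e-12))
  }
})

test_that("trees serialize to Newick with pattern leaf labels", {
  set.seed(29)
  m <- rbind(matrix(rep(c(1L, 0L, 1L), 20), 20, 3, byrow = TRUE),
             matrix(rep(c(0L, 1L, 1L), 20), 20, 3, byrow = TRUE),
             matrix(rep(c(1L, 1L, 1L), 20), 20, 3, byrow = TRUE))
  S <- matrix(runif(60 * 5, 0.5, 2), 60, 5)
  cls <- enumerate_classes(make_presence(m), S)
  tr <- ward_tree(cls)
  txt <- tree_newick(tr)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, cls$classes$pattern)
})

test_that("fingerprints are leaf distributions and entropy is Shannon's", {
  m <- rbind(matrix(rep(c(1L, 0L), 25), 25, 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 75), 75, 2, byrow = TRUE))
  S <- matrix(runif(100 * 4, 0.5, 2), 100, 4)
  cls <- enumerate_classes(make_presence(m), S)
  tr <- ward_tree(cls)
  fp <- fingerprint(1:100, cls, tr)
  expect_equal(sum(fp), 1, tolerance = 1e-12)
  expect_setequal(as.numeric(fp), c(0.25, 0.75))

  # ROI inside one leaf: delta distribution, entropy 0
  fp_delta <- fingerprint(1:25, cls, tr)
  expect_setequal(as.numeric(fp_delta), c(0, 1))
  expect_equal(fingerprint_entropy(fp_delta), 0)

  # uniform over n leaves: entropy ln n
  expect_equal(fingerprint_entropy(rep(1 / 7, 7)), log(7), tolerance = 1e-12)
  expect_equal(fingerprint_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  expect_equal(fingerprint_entropy(c(0.5, 0.5), base = 2), 1)

  # ROI of only null-class pixels errors
  m0 <- rbind(m, matrix(0L, 5, 2))
  cls0 <- enumerate_classes(make_presence(m0),
                            rbind(S, matrix(1, 5, 4)))
  tr0 <- ward_tree(cls0)
  expect_error(fingerprint(101:105, cls0, tr0), "null-class")
})

test_that("classes group spectra of similar shape on rendered scenes", {
  sc <- render_phantom(noise_sd = 0.5, seed = 5)
  S <- spectra_matrix(sc)
  fit <- nmf_unmix(S, nmf_params(k = 9, max_iter = 150))
  pr <- binarize_presence(fit$W)
  cls <- enumerate_classes(pr, S)
  expect_lte(nrow(cls$classes), 2^6)

  # within-class variance of normalized spectra below between-class variance
  nrm <- S / pmax(sqrt(rowSums(S^2)), 1e-300)
  keep <- !is.na(cls$assignment)
  grand <- colMeans(nrm[keep, ])
  within <- 0; between <- 0
  for (ci in seq_along(cls$members)) {
    idx <- cls$members[[ci]]
    mu <- colMeans(nrm[idx, , drop = FALSE])
    within <- within + sum(sweep(nrm[idx, , drop = FALSE], 2, mu)^2)
    between <- between + length(idx) * sum((mu - grand)^2)
  }
  expect_lt(within / between, 1)
})
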