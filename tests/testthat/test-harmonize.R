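test_that("quantile normalization hits the mean order statistics", {
  m <- expr_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                          dimnames = list(paste0("g", 1:3), c("a", "b"))))
  q <- unclass(quantile_normalize(m))
  # hand computation: reference = rowMeans of sorted columns
  expect_equal(q[, "a"], c(g1 = 2.5, g2 = 3.5, g3 = 4.5))
  expect_equal(q[, "a"], q[, "b"], ignore_attr = TRUE)

  # fixed point on identical columns
  m2 <- expr_matrix(matrix(c(2, 7, 1, 2, 7, 1), 3, 2,
                           dimnames = list(paste0("g", 1:3), c("a", "b"))))
  expect_equal(unclass(quantile_normalize(m2)), unclass(m2))

  # ties share the mean of their target quantiles (brute force on 3-vectors)
  m3 <- expr_matrix(matrix(c(1, 1, 2, 0, 2, 4), 3, 2,
                           dimnames = list(paste0("g", 1:3), c("a", "b"))))
  q3 <- unclass(quantile_normalize(m3))
  ref <- rowMeans(cbind(sort(m3[, 1]), sort(m3[, 2])))
  expect_equal(unname(q3[1:2, "a"]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(q3[3, "a"]), unname(ref[3]))

  expect_warning(quantile_normalize(expr_matrix(m[, 1, drop = FALSE])), ">=2 samples")
})

test_that("quantile normalization invariants hold and match limma", {
  set.seed(5)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  q <- unclass(quantile_normalize(expr_matrix(m)))
  ref <- unname(sort(q[, 1]))
  for (j in 2:10) expect_equal(unname(sort(q[, j])), ref, tolerance = 1e-12)
  expect_identical(dimnames(q), dimnames(m))
  # independent oracle
  expect_equal(q, limma::normalizeQuantiles(m, ties = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("EB batch correction removes a planted location shift", {
  set.seed(3)
  g <- 60; n <- 100
  shift <- rnorm(g, 3, 1)   # gene-varying batch effect
  x <- cbind(matrix(rnorm(g * n), g, n), matrix(rnorm(g * n) + shift, g, n))
  dimnames(x) <- list(paste0("g", 1:g), paste0("s", 1:(2 * n)))
  batch <- rep(c("A", "B"), each = n)
  xc <- unclass(eb_batch_correct(expr_matrix(x), batch))
  d <- rowMeans(xc[, batch == "A"]) - rowMeans(xc[, batch == "B"])
  expect_lt(mean(abs(d)), 0.1)
  expect_identical(dimnames(xc), dimnames(x))

  # statistically identical batches: output close to input
  set.seed(4)
  x0 <- matrix(rnorm(g * 2 * n), g, 2 * n, dimnames = dimnames(x))
  xc0 <- unclass(eb_batch_correct(expr_matrix(x0), batch))
  expect_lt(mean(abs(rowMeans(xc0) - rowMeans(x0))), 0.05)

  expect_error(eb_batch_correct(expr_matrix(x0), rep("A", 2 * n)), ">=2 batches")
  expect_error(eb_batch_correct(expr_matrix(x0), c("B", rep("A", 2 * n - 1))),
               ">=2 samples")
})

test_that("cPCA+MNN removes a gross global offset between sources", {
  set.seed(4)
  g <- 40
  tum <- matrix(rnorm(g * 60, 5), g, 60,
                dimnames = list(paste0("g", 1:g), paste0("t", 1:60)))
  mod <- tum[, 1:20] + 10
  colnames(mod) <- paste0("m", 1:20)
  al <- cpca_mnn_align(expr_matrix(tum), expr_matrix(mod),
                       harmonization_config("cpca_mnn"))
  d0 <- mean(sqrt(colSums((tum[, 1:20] - mod)^2)))
  d1 <- mean(sqrt(colSums((unclass(al$tumor)[, 1:20] - unclass(al$model))^2)))
  expect_gt(1 - d1 / d0, 0.9)
  expect_identical(colnames(al$model), colnames(mod))
})

test_that("cPCA step removes a planted tumor-only variance direction", {
  set.seed(6)
  g <- 30
  v <- rnorm(g); v <- v / sqrt(sum(v^2))     # contamination axis
  tum <- matrix(rnorm(g * 80, 0, 1), g, 80) + v %*% t(rnorm(80, 0, 4))
  mod <- matrix(rnorm(g * 30, 0, 1), g, 30)
  dimnames(tum) <- list(paste0("g", 1:g), paste0("t", 1:80))
  dimnames(mod) <- list(paste0("g", 1:g), paste0("m", 1:30))
  al <- cpca_mnn_align(expr_matrix(tum), expr_matrix(mod),
                       harmonization_config("cpca_mnn", n_cpc_remove = 2, mnn_k = 0))
  var0 <- var(as.vector(t(v) %*% tum))
  var1 <- var(as.vector(t(v) %*% unclass(al$tumor)))
  expect_gt(1 - var1 / var0, 0.8)
})

test_that("no-op configuration leaves both matrices unchanged", {
  set.seed(7)
  tum <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("t", 1:10)))
  mod <- matrix(rnorm(100), 20, 5,
                dimnames = list(paste0("g", 1:20), paste0("m", 1:5)))
  al <- cpca_mnn_align(expr_matrix(tum), expr_matrix(mod),
                       harmonization_config("cpca_mnn", n_cpc_remove = 0, mnn_k = 0))
  expect_equal(unclass(al$tumor), tum, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(al$model), mod, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cPCA+MNN is invariant to gene permutation", {
  set.seed(8)
  g <- 25
  tum <- matrix(rnorm(g * 40, 5), g, 40,
                dimnames = list(paste0("g", 1:g), paste0("t", 1:40)))
  mod <- matrix(rnorm(g * 12, 8), g, 12,
                dimnames = list(paste0("g", 1:g), paste0("m", 1:12)))
  cfg <- harmonization_config("cpca_mnn", n_cpc_remove = 2)
  a <- cpca_mnn_align(expr_matrix(tum), expr_matrix(mod), cfg)
  perm <- sample(g)
  b <- cpca_mnn_align(expr_matrix(tum[perm, ]), expr_matrix(mod[perm, ]), cfg)
  expect_equal(unclass(b$model)[order(perm), ], unclass(a$model),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(b$tumor)[order(perm), ], unclass(a$tumor),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("harmonize dispatches and preserves shapes and sample ids", {
  set.seed(9)
  tum <- expr_matrix(matrix(rnorm(100, 5), 10, 10,
                            dimnames = list(paste0("g", 1:10), paste0("t", 1:10))))
  mod <- expr_matrix(matrix(rnorm(50, 7), 10, 5,
                            dimnames = list(paste0("g", 1:10), paste0("m", 1:5))))
  none <- harmonize(tum, mod, harmonization_config("none"))
  expect_equal(unclass(none$tumor), unclass(tum))
  expect_identical(none$provenance$method, "none")

  for (m in c("quantile", "eb_batch", "cpca_mnn")) {
    h <- harmonize(tum, mod, harmonization_config(m, n_cpc_remove = 2))
    expect_identical(dim(h$tumor), dim(tum))
    expect_identical(colnames(h$model), colnames(mod))
  }
  # joint quantile normalization equalizes all columns of the two outputs
  h <- harmonize(tum, mod, harmonization_config("quantile"))
  joint <- cbind(unclass(h$tumor), unclass(h$model))
  ref <- unname(sort(joint[, 1]))
  for (j in 2:ncol(joint))
    expect_equal(unname(sort(joint[, j])), ref, tolerance = 1e-12)

  expect_error(harmonize(tum, mod, list(method = "none")), "harmonization_config")
})
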