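test_that("robust center/scale matches hand computation and is consistent", {
  rcs <- robust_center_scale(c(1, 2, 3, 4, 5))
  expect_equal(rcs$mu_hat, 3)
  expect_equal(rcs$s_hat, 1.4826)   # 1.4826 * median(|{-2,-1,0,1,2}|)
  expect_false(rcs$degenerate)

  expect_true(robust_center_scale(rep(2, 5))$degenerate)
  expect_error(robust_center_scale(1:2), ">=3")

  set.seed(1)
  big <- robust_center_scale(rnorm(10000))
  expect_lt(abs(big$s_hat - 1), 0.05)     # MAD consistency for the normal

  sd_pol <- robust_center_scale(c(1, 2, 3, 4, 100), sigma_policy = "sd")
  expect_equal(sd_pol$sigma_hat, sd(c(1, 2, 3, 4, 100)))
})

test_that("deviance score identities hold exactly", {
  rcs <- robust_center_scale(c(1, 2, 3, 4, 5))
  expect_equal(as.numeric(ds_sda(rcs$mu_hat, rcs)), 0)
  expect_equal(as.numeric(ds_sda(rcs$mu_hat + 2 * rcs$s_hat, rcs)), 2)
  d <- 0.7
  expect_equal(as.numeric(ds_sda(rcs$mu_hat + d, rcs)),
               as.numeric(ds_sda(rcs$mu_hat - d, rcs)))
  # exact monotone ranking at planted distances
  dd <- c(0, 0.5, 1, 2)
  expect_equal(as.numeric(ds_sda(rcs$mu_hat + dd * rcs$s_hat, rcs)), dd)
  expect_equal(attr(ds_sda(rcs$mu_hat - rcs$s_hat, rcs), "signed"), -1)

  expect_error(ds_sda(1, robust_center_scale(rep(1, 3))), "degenerate")
})

test_that("congruence p-value follows the normal tail", {
  rcs <- robust_center_scale(c(1, 2, 3, 4, 5))
  expect_equal(ds_pvalue(rcs$mu_hat, rcs), 1)
  expect_equal(ds_pvalue(rcs$mu_hat + 1.959964 * rcs$sigma_hat, rcs), 0.05,
               tolerance = 1e-6)
  p <- ds_pvalue(rcs$mu_hat + seq(0, 3, by = 0.1) * rcs$sigma_hat, rcs)
  expect_true(all(diff(p) < 0))
})

test_that("bootstrap CI is deterministic and follows the percentile rule", {
  set.seed(2)
  tum <- rnorm(150)
  ci1 <- bootstrap_ci(1.3, tum, b = 400, seed = 9)
  ci2 <- bootstrap_ci(1.3, tum, b = 400, seed = 9)
  expect_identical(ci1[c("ci_low", "ci_high")], ci2[c("ci_low", "ci_high")])

  # independent percentile computation on the stored replicate vector
  lg <- log2(ci1$replicates)
  q <- quantile(lg, c(0.025, 0.975), type = 7, names = FALSE)
  expect_equal(c(ci1$ci_low, ci1$ci_high), 2^q, tolerance = 1e-12)
  expect_true(ci1$ci_low <= ci1$ci_high && ci1$ci_low > 0)

  # width shrinks with tumor sample size
  set.seed(3)
  w <- sapply(c(100, 5000), function(n) {
    ci <- bootstrap_ci(2, rnorm(n), b = 500, seed = 4)
    log2(ci$ci_high) - log2(ci$ci_low)
  })
  expect_lt(w[2], w[1])
})

test_that("gene deviance matches hand computations", {
  tum <- c(1, 2, 3, 4, 5)     # median 3, scaled MAD 1.4826
  expect_equal(ds_gene(3, tum), 0)
  expect_equal(ds_gene(3 + 1.4826, tum), 1)
  expect_equal(ds_gene(3 - 2 * 1.4826, tum), -2)
  # zero-MAD gene excluded as NA
  tm <- rbind(g1 = tum, g2 = rep(7, 5))
  expect_equal(unname(ds_gene(c(3, 7), tm)), c(0, NA))
  expect_error(ds_gene(1, c(1, 2)), ">=3")
})

test_that("pathway deviance is a geometric mean with sane edge behavior", {
  expect_equal(ds_path(c(1, 4)), 2)
  expect_equal(ds_path(c(2, -2, 2)), 2)
  expect_equal(ds_path(c(0.5, 2)), 1)
  expect_equal(ds_path(c(0, 3)), 0)          # zero limit
  expect_equal(ds_path(c(NA, 2)), 2)         # NA excluded
  expect_error(ds_path(NA_real_), "no usable")

  # scale equivariance and permutation invariance
  v <- c(0.3, 1.7, 2.5, 0.9)
  expect_equal(ds_path(3 * v), 3 * ds_path(v))
  expect_equal(ds_path(sample(v)), ds_path(v))
  # bounded by min and max of |values|
  expect_true(ds_path(v) >= min(abs(v)) && ds_path(v) <= max(abs(v)))
})

test_that("empirical pathway p-value uses the add-one rule", {
  null99 <- seq_len(99) / 100
  expect_equal(ds_path_pvalue(2, null99), 1 / 100)      # above all null values
  expect_equal(ds_path_pvalue(0, null99), 1)            # below all null values
  odd <- seq_len(9)
  expect_equal(ds_path_pvalue(5, odd), (1 + 5) / 10)    # direct count at median
  expect_error(ds_path_pvalue(1, numeric(0)), "empty")
})

test_that("leave-one-out tumor null has no self-bias", {
  set.seed(4)
  tum <- matrix(rnorm(20 * 40), 20, 40,
                dimnames = list(paste0("g", 1:20), paste0("t", 1:40)))
  null <- tumor_pathway_null(tum, list(P = paste0("g", 1:10)))
  expect_identical(dim(null), c(1L, 40L))
  # scored against statistics including itself, values would collapse toward 0;
  # leave-one-out keeps them near the |N(0,1)| geometric mean (~0.66)
  expect_gt(median(null), 0.4)
  expect_lt(median(null), 1.1)
})

test_that("deviance_table assembles records for planted models", {
  sim <- simulate_scenario(scenario_config(seed = 42))
  fit <- fit_sda(sim$tumor, sim$annotation, target = "subtypeA",
                 gamma = 100, lam = 5)
  dev <- deviance_table(fit, sim$tumor, sim$models, sim$annotation, "subtypeA",
                        b = 200, seed = 1)
  expect_identical(dev$model_id, colnames(sim$models))
  expect_true(all(dev$ci_low <= dev$ci_high))
  expect_true(all(dev$pval >= 0 & dev$pval <= 1))
  # genome-wide distances recover the planted ordering
  dist_order <- order(sim$truth$model_congruence$d[1:4])
  expect_identical(order(dev$ds_sda[1:4]), dist_order)
  # CI brackets the deviance point estimate for the well-separated distractor
  i3 <- which(dev$model_id == "distractor_d3")
  expect_true(dev$ci_low[i3] < dev$ds_sda[i3] && dev$ds_sda[i3] < dev$ci_high[i3])
})
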