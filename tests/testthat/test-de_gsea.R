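test_that("planted fold changes are detected and the DE rule is a conjunction", {
  set.seed(1)
  g <- 50; n <- 50
  x <- matrix(rnorm(g * 2 * n, 5, 0.3), g, 2 * n,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:(2 * n))))
  x[1, 1:n] <- x[1, 1:n] + 1          # log2FC = 1 (2-fold)
  lab <- rep(c("A", "B"), each = n)
  de <- differential_expression(expr_matrix(x), lab, target = "A")
  expect_true(de$is_de[de$gene == "g1"])
  expect_equal(de$log2fc[de$gene == "g1"], 1, tolerance = 0.2)

  # |FC| above threshold but adjusted p too large -> not DE
  tab <- as_de_result(data.frame(gene = "x", log2fc = 1, pval = 0.1,
                                 adj_pval = 0.2))
  expect_false(tab$is_de)
  # significant but below fold-change threshold -> not DE
  tab2 <- as_de_result(data.frame(gene = "x", log2fc = 0.3, pval = 1e-6,
                                  adj_pval = 1e-5))
  expect_false(tab2$is_de)

  expect_error(differential_expression(expr_matrix(x), c("A", "A", rep("B", 98)),
                                       target = "A"), ">=3")
})

test_that("null data keeps the BH false-positive proportion controlled", {
  fp <- replicate(20, {
    x <- matrix(rnorm(1000 * 40, 5, 0.5), 1000, 40,
                dimnames = list(paste0("g", 1:1000), paste0("s", 1:40)))
    de <- differential_expression(expr_matrix(x), rep(c("A", "B"), each = 20),
                                  target = "A")
    mean(de$is_de)
  })
  expect_lte(mean(fp), 0.05 + 0.03)
})

test_that("BH adjustment is monotone and never below the raw p-value", {
  set.seed(2)
  x <- matrix(rnorm(100 * 20, 5, 0.5), 100, 20,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:20)))
  de <- differential_expression(expr_matrix(x), rep(c("A", "B"), each = 10),
                                target = "A")
  expect_true(all(de$adj_pval >= de$pval))
  ord <- order(de$pval)
  expect_true(all(diff(de$adj_pval[ord]) >= -1e-12))
})

test_that("negative-binomial Wald backend works on counts", {
  sim <- simulate_scenario(scenario_config(n_genes = 30, n_signature_genes = 8,
                                           n_tumor_k = 25, n_tumor_other = 25,
                                           pathway_spec = list(P = 1:8),
                                           model_congruence = data.frame(
                                             model_id = "m0", d = 0,
                                             discordant_pathway = NA,
                                             discordance = 0),
                                           seed = 11),
                           emit_counts = TRUE)
  expect_identical(expr_scale(sim$tumor_counts), "counts")
  de <- differential_expression(sim$tumor_counts, sim$annotation,
                                target = "subtypeA", method = "nb_wald")
  sig <- de$gene %in% sim$truth$de_genes
  expect_gt(mean(de$is_de[sig]), 0.8)          # planted signal found
  expect_lt(mean(de$is_de[!sig]), 0.3)
  expect_error(differential_expression(sim$tumor, sim$annotation,
                                       target = "subtypeA", method = "nb_wald"),
               "counts")
})

test_that("enrichment p-values match exhaustive enumeration on a tiny universe", {
  set.seed(21)
  r <- setNames(rnorm(10), paste0("g", 1:10))
  set3 <- c("g2", "g5", "g9")
  out <- preranked_gsea(r, list(P = set3), n_perm = 10000, seed = 3)
  expect_equal(out$es, es_oracle(set3, r), tolerance = 1e-12)

  null_all <- apply(combn(10, 3), 2, function(ii) es_oracle(names(r)[ii], r))
  p_exact <- mean(abs(null_all) >= abs(out$es) - 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(out$pval - p_exact), 2 * mc_se + 1 / 10001)
})

test_that("a planted top pathway is strongly enriched", {
  set.seed(22)
  r <- setNames(sort(rnorm(200, 0, 1), decreasing = TRUE), paste0("g", 1:200))
  out <- preranked_gsea(r, list(top = paste0("g", 1:20)), n_perm = 10000, seed = 5)
  expect_gt(out$nes, 0)
  expect_lt(out$adj_pval, 0.05)
  expect_identical(out$size, 20L)
})

test_that("rank negation flips every NES exactly and keeps p-values", {
  set.seed(23)
  r <- setNames(rnorm(60), paste0("g", 1:60))
  sets <- list(A = paste0("g", sample(60, 8)), B = paste0("g", sample(60, 15)))
  a <- preranked_gsea(r, sets, n_perm = 1000, seed = 7)
  b <- preranked_gsea(-r, sets, n_perm = 1000, seed = 7)
  expect_equal(a$nes, -b$nes, tolerance = 1e-12)
  expect_identical(a$pval, b$pval)
})

test_that("zero weighting reduces to the classical KS statistic", {
  set.seed(24)
  r <- setNames(rnorm(10), paste0("h", 1:10))
  set4 <- c("h1", "h4", "h8", "h9")
  out <- preranked_gsea(r, list(P = set4), n_perm = 50, weight_p = 0, seed = 1)
  expect_equal(out$es, es_oracle(set4, r, p = 0), tolerance = 1e-12)
})

test_that("gsea input validation", {
  r <- setNames(rnorm(5), paste0("g", 1:5))
  expect_error(preranked_gsea(numeric(0), list(P = "g1")), "empty")
  expect_error(preranked_gsea(r, list(P = paste0("g", 1:5))), "as large as")
  # pathways below min_size are dropped
  out <- preranked_gsea(r, list(P = c("g1", "g2")), n_perm = 10, min_size = 3)
  expect_identical(nrow(out), 0L)
})

test_that("pathway filters apply the strict printed rules and honor pins", {
  enr <- data.frame(pathway = c("big", "small", "weak", "edge30", "edge200", "pin"),
                    es = 1, nes = c(-1.8, 1.6, 0.9, 1.7, -1.9, 0.854),
                    pval = 0.01, adj_pval = 0.02,
                    size = c(100, 25, 120, 30, 200, 80))
  sets <- list(big = paste0("g", 1:22), small = paste0("g", 1:25),
               weak = paste0("g", 1:30), edge30 = paste0("g", 1:30),
               edge200 = paste0("g", 1:40), pin = paste0("g", 1:21))
  de <- data.frame(gene = paste0("g", 1:40), log2fc = 2,
                   pval = 1e-5, adj_pval = 1e-4, is_de = TRUE)
  out <- filter_pathways(enr, de, sets)

  expect_setequal(out$analysis$pathway,
                  c("big", "small", "weak", "edge30", "edge200", "pin"))
  # selection: n_de > 20 & 30 < size < 200 & |NES| > 1.5, strict everywhere
  expect_setequal(out$selection$pathway[!out$selection$pinned], "big")

  pinned <- filter_pathways(enr, de, sets, pinned = "pin")
  expect_true("pin" %in% pinned$selection$pathway)
  expect_true(pinned$selection$pinned[pinned$selection$pathway == "pin"])

  # idempotent and order-independent
  shuffled <- enr[c(4, 2, 6, 1, 3, 5), ]
  out2 <- filter_pathways(shuffled, de, sets, pinned = "pin")
  expect_identical(pinned$selection, out2$selection)

  # n_de boundary is strict: exactly 20 DE genes fails
  de20 <- de; de20$is_de <- de20$gene %in% paste0("g", 1:20)
  out3 <- filter_pathways(enr, de20, sets)
  expect_false("big" %in% out3$analysis$pathway)
})
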