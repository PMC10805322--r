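# shared helpers: tiny in-code fixtures, no files shipped

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# small two-class expression matrix with a planted mean difference on the
# first `n_sig` genes; returns list(x, labels)
make_two_class <- function(n_per_class = 30, g = 10, n_sig = 2, effect = 3,
                           noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  mu <- c(rep(effect / 2, n_sig), rep(0, g - n_sig))
  a <- matrix(rnorm(g * n_per_class, mu, noise_sd), g, n_per_class)
  b <- matrix(rnorm(g * n_per_class, -mu, noise_sd), g, n_per_class)
  x <- cbind(a, b)
  dimnames(x) <- list(sprintf("g%02d", seq_len(g)),
                      sprintf("s%03d", seq_len(2 * n_per_class)))
  list(x = expr_matrix(x),
       labels = rep(c("A", "B"), each = n_per_class))
}

# straight-line dense two-class LDA direction on standardized data (oracle)
lda_direction <- function(x, labels) {
  xs <- scale(t(unclass(x)))
  cls <- unique(labels)
  m1 <- colMeans(xs[labels == cls[1], , drop = FALSE])
  m2 <- colMeans(xs[labels == cls[2], , drop = FALSE])
  sw <- (crossprod(sweep(xs[labels == cls[1], , drop = FALSE], 2, m1)) +
           crossprod(sweep(xs[labels == cls[2], , drop = FALSE], 2, m2))) /
    (nrow(xs) - 2)
  solve(sw, m1 - m2)
}

# straight-line weighted-KS enrichment score (oracle, independent of es_stat)
es_oracle <- function(set, ranks, p = 1) {
  srt <- names(ranks)[order(ranks, decreasing = TRUE)]
  hit <- srt %in% set
  w <- abs(ranks[srt])^p
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}
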