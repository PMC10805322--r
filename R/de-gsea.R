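#' Differential expression between the two tumor subtypes
#'
#' Default backend \code{"welch_log"}: per-gene Welch t-test on log2
#' expression; the effect is the difference of class means on the log2 scale
#' (= log2 fold change), target class minus comparison. Backend
#' \code{"nb_wald"} fits a per-gene negative-binomial GLM with a class factor
#' and a log-library-size offset on raw counts and Wald-tests the class
#' coefficient (a simplified single-factor analogue of count-based DE tools;
#' no shrinkage or outlier refitting is attempted). A gene is flagged DE when
#' |fold change| exceeds \code{fc_threshold} AND the BH-adjusted p-value is
#' below \code{alpha}.
#'
#' Externally computed DE tables (e.g. from DESeq2) can be injected anywhere a
#' DE result is consumed: any data frame with columns \code{gene},
#' \code{log2fc}, \code{pval}, \code{adj_pval} passes [as_de_result()].
#'
#' @param tumor tumor [expr_matrix()]; \code{scale="counts"} required for
#'   \code{"nb_wald"}.
#' @param labels [sample_annotation()] or label vector in column order.
#' @param target target class label.
#' @param method test backend.
#' @param fc_threshold fold-change threshold on the natural scale (default
#'   1.5, i.e. |log2FC| > log2(1.5)).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data frame: \code{gene}, \code{log2fc}, \code{pval},
#'   \code{adj_pval}, \code{is_de}.
#' @export
differential_expression <- function(tumor, labels, target = NULL,
                                    method = c("welch_log", "nb_wald"),
                                    fc_threshold = 1.5, alpha = 0.05) {
  method <- match.arg(method)
  m <- as_plain(tumor)
  if (inherits(labels, "sample_annotation") || is.data.frame(labels)) {
    if (is.null(target)) {
      lab0 <- labels$class_label[match(colnames(m), labels$sample_id)]
      target <- lab0[!is.na(lab0)][1L]
    }
    y <- training_labels(labels, colnames(m), target)
  } else {
    lev <- unique(as.character(labels))
    if (length(lev) != 2L) stop("exactly two classes required")
    if (is.null(target)) target <- lev[1L]
    y <- factor(as.character(labels), levels = c(target, setdiff(lev, target)))
  }
  if (any(table(y) < 3L)) stop("each class needs >=3 samples")

  if (method == "welch_log") {
    a <- m[, y == levels(y)[1L], drop = FALSE]
    b <- m[, y == levels(y)[2L], drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1L)
    vb <- rowSums((b - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    pval <- 2 * stats::pt(-abs(tstat), df)
    pval[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
    log2fc <- ma - mb
  } else {
    if (expr_scale(tumor) != "counts") stop("nb_wald requires scale=\"counts\"")
    off <- log(colSums(m))
    cls <- as.integer(y == levels(y)[1L])
    res <- t(apply(m, 1L, function(cts) {
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(cts ~ cls + offset(off))),
        error = function(e) NULL)
      if (is.null(fit)) return(c(NA_real_, NA_real_))
      s <- summary(fit)$coefficients
      c(s["cls", "Estimate"] / log(2), s["cls", "Pr(>|z|)"])
    }))
    log2fc <- res[, 1L]; pval <- res[, 2L]
  }
  adj <- stats::p.adjust(pval, method = "BH")
  data.frame(gene = rownames(m), log2fc = log2fc, pval = pval, adj_pval = adj,
             is_de = !is.na(adj) & abs(log2fc) > log2(fc_threshold) & adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate an (external) differential-expression table
#' @param df data frame with columns \code{gene}, \code{log2fc}, \code{pval},
#'   \code{adj_pval}; \code{is_de} is recomputed if absent.
#' @param fc_threshold,alpha DE rule, see [differential_expression()].
#' @export
as_de_result <- function(df, fc_threshold = 1.5, alpha = 0.05) {
  need <- c("gene", "log2fc", "pval", "adj_pval")
  if (!all(need %in% names(df)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("duplicate genes in DE table")
  if (is.null(df$is_de))
    df$is_de <- !is.na(df$adj_pval) &
      abs(df$log2fc) > log2(fc_threshold) & df$adj_pval < alpha
  df
}

# weighted-KS enrichment score for hit positions `h` (sorted ascending) in a
# ranked list of length n with hit weights w (|rank|^p at the hit positions).
# Returns the signed maximum deviation of the running statistic. Exact
# |max| == |min| ties (common rationals from the miss-step side) are broken by
# the walk's total area, which negates exactly under list reversal, keeping
# the statistic antisymmetric under rank negation.
es_stat <- function(h, w, n) {
  s <- length(h)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, s); nr <- s }   # all-zero ranks: fall back to unweighted
  cum_hit <- cumsum(w) / nr
  miss_step <- 1 / (n - s)
  peak <- cum_hit - (h - seq_len(s)) * miss_step          # just after each hit
  trough <- cum_hit - w / nr - (h - seq_len(s)) * miss_step # just before each hit
  hi <- max(peak); lo <- min(trough, 0)
  if (hi + lo > 1e-9) return(hi)
  if (hi + lo < -1e-9) return(lo)
  # area of the piecewise-linear walk (O(s) arithmetic-series form)
  len <- c(h, n + 1L)[-1L] - h                 # run lengths from each hit on
  area <- -miss_step * (h[1L] - 1) * h[1L] / 2 +
    sum(len * peak - miss_step * (len - 1) * len / 2)
  if (area >= 0) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a ranked gene list
#' (genes sorted by decreasing rank metric, typically the log2 fold change of
#' all genes). Hit increments are \eqn{|r|^{weight\_p}} (classical unweighted
#' KS at \code{weight_p = 0}); the enrichment score ES is the signed maximum
#' deviation. The null is built from \code{n_perm} random gene sets of the
#' same size drawn from the ranked universe; \eqn{NES = ES / mean(|ES_{null}|
#' \ of\ matching\ sign)} and the two-sided empirical p-value is the add-one
#' estimator \eqn{(1 + \#\{|ES_{null}| \ge |ES|\})/(1 + n_{perm})}, BH-adjusted
#' across pathways.
#'
#' @param ranks named numeric vector, gene -> rank metric.
#' @param sets named list of gene sets (restricted internally to ranked
#'   genes).
#' @param n_perm number of random gene sets per pathway (default 10000).
#' @param weight_p rank weighting exponent (default 1).
#' @param min_size pathways with fewer than this many ranked genes are
#'   dropped (default 3).
#' @param seed integer seed for the permutation draws.
#' @return data frame: \code{pathway}, \code{es}, \code{nes}, \code{pval},
#'   \code{adj_pval}, \code{size}.
#' @export
preranked_gsea <- function(ranks, sets, n_perm = 10000L, weight_p = 1,
                           min_size = 3L, seed = 1L) {
  if (length(ranks) == 0L) stop("empty rank vector")
  if (is.null(names(ranks)) || anyDuplicated(names(ranks)))
    stop("ranks must be uniquely named by gene")
  ord <- order(ranks, decreasing = TRUE)
  r_sorted <- ranks[ord]
  genes_sorted <- names(r_sorted)
  n <- length(r_sorted)
  wts <- abs(r_sorted)^weight_p

  sizes <- vapply(sets, function(g) sum(g %in% genes_sorted), integer(1))
  if (any(sizes >= n))
    stop("pathway as large as the ranked universe: ",
         paste(names(sets)[sizes >= n], collapse = ", "))
  keep <- sizes >= min_size
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0L)
    return(data.frame(pathway = character(0), es = numeric(0), nes = numeric(0),
                      pval = numeric(0), adj_pval = numeric(0),
                      size = integer(0), stringsAsFactors = FALSE))

  set.seed(seed)
  # one shared null per distinct size keeps n_perm draws comparable across
  # pathways. Null sets are drawn as gene subsets in the *input* gene order
  # (not positions in the sorted list), so the draws do not depend on the rank
  # values and negating every rank negates every null ES exactly.
  pos <- integer(n); pos[ord] <- seq_len(n)
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
      h <- sort.int(pos[sample.int(n, s)])
      es_stat(h, wts[h], n)
    }, numeric(1))
  }
  es <- nes <- pv <- numeric(length(sets))
  for (i in seq_along(sets)) {
    h <- sort.int(which(genes_sorted %in% sets[[i]]))
    es[i] <- es_stat(h, wts[h], n)
    null <- null_by_size[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i])]
    nes[i] <- if (length(same) > 0L) es[i] / mean(abs(same)) else NA_real_
    pv[i] <- (1 + sum(abs(null) >= abs(es[i]))) / (1 + n_perm)
  }
  data.frame(pathway = names(sets), es = es, nes = nes, pval = pv,
             adj_pval = stats::p.adjust(pv, method = "BH"),
             size = as.integer(sizes), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter pathways for mechanistic scoring and final selection
#'
#' Two nested pathway lists with the strict boundary rules: the
#' \emph{analysis} set keeps pathways with more than \code{min_de} DE genes;
#' the \emph{selection} set additionally requires \code{size_low} < size <
#' \code{size_high} and |NES| > \code{nes_abs}. User-pinned pathways (prior
#' biological knowledge) are appended to the selection set with a
#' \code{pinned} flag regardless of the thresholds and are excluded from any
#' average built on the unbiased selection set.
#'
#' @param enr enrichment table from [preranked_gsea()].
#' @param de DE table (see [differential_expression()] / [as_de_result()]).
#' @param sets the gene-set list the enrichment was computed on.
#' @param min_de,size_low,size_high,nes_abs filter thresholds (strict
#'   inequalities; defaults 20, 30, 200, 1.5).
#' @param pinned character vector of pathway names to carry through.
#' @return list with data frames \code{analysis} and \code{selection}; the
#'   selection table has columns \code{pathway}, \code{nes}, \code{size},
#'   \code{n_de}, \code{pinned}.
#' @export
filter_pathways <- function(enr, de, sets, min_de = 20L, size_low = 30L,
                            size_high = 200L, nes_abs = 1.5,
                            pinned = character(0)) {
  de <- as_de_result(de)
  de_genes <- de$gene[de$is_de]
  n_de <- vapply(enr$pathway, function(p)
    sum(sets[[p]] %in% de_genes), integer(1))
  tab <- data.frame(pathway = enr$pathway, nes = enr$nes, size = enr$size,
                    n_de = n_de, row.names = NULL, stringsAsFactors = FALSE)
  analysis <- tab[tab$n_de > min_de, , drop = FALSE]
  sel <- analysis[analysis$size > size_low & analysis$size < size_high &
                    !is.na(analysis$nes) & abs(analysis$nes) > nes_abs, ,
                  drop = FALSE]
  sel$pinned <- logical(nrow(sel))
  extra <- setdiff(intersect(pinned, tab$pathway), sel$pathway)
  if (length(extra) > 0L) {
    add <- tab[match(extra, tab$pathway), , drop = FALSE]
    add$pinned <- TRUE
    sel <- rbind(sel, add)
  }
  sel$pinned[sel$pathway %in% pinned] <- TRUE
  rownames(analysis) <- rownames(sel) <- NULL
  list(analysis = analysis, selection = sel[order(sel$pathway), , drop = FALSE])
}
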