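#' Robust center and scale of the tumor projections
#'
#' The target-class tumor projections are summarized by their median
#' \eqn{\hat\mu_k} and scaled median absolute deviation \eqn{\hat s =
#' c \cdot median(|t - \hat\mu_k|)} (consistency constant \eqn{c = 1.4826}
#' for the normal by default). The dispersion \eqn{\hat\sigma} used by the
#' p-value is \eqn{\hat s} under the default \code{"mad"} policy, or the
#' sample standard deviation under \code{"sd"}.
#'
#' @param tumor_proj numeric vector of target-class tumor projections (>= 3).
#' @param mad_constant MAD consistency constant (default 1.4826).
#' @param sigma_policy dispersion used for the normal-tail p-value.
#' @return list of class \code{robust_center_scale}: \code{mu_hat},
#'   \code{s_hat}, \code{sigma_hat}, \code{n}, \code{degenerate}.
#' @export
robust_center_scale <- function(tumor_proj, mad_constant = 1.4826,
                                sigma_policy = c("mad", "sd")) {
  sigma_policy <- match.arg(sigma_policy)
  v <- as.numeric(tumor_proj)
  if (length(v) < 3L) stop("need >=3 tumor projections")
  mu <- stats::median(v)
  s <- mad_constant * stats::median(abs(v - mu))
  structure(list(mu_hat = mu, s_hat = s,
                 sigma_hat = if (sigma_policy == "mad") s else stats::sd(v),
                 n = length(v), degenerate = s == 0,
                 mad_constant = mad_constant, sigma_policy = sigma_policy),
            class = "robust_center_scale")
}

#' Genome-wide deviance score on the discriminant axis
#'
#' \eqn{DS(i,k) = |c_i - \hat\mu_k| / \hat s}: the robust standardized
#' distance of model projection \eqn{c_i} to the tumor-cohort center. Smaller
#' values indicate higher congruence. The signed difference
#' \eqn{(c_i - \hat\mu_k)/\hat s} is returned as attribute \code{"signed"}.
#'
#' @param c_i numeric vector of model projections.
#' @param rcs a non-degenerate [robust_center_scale()].
#' @return numeric vector of deviance scores (>= 0).
#' @export
ds_sda <- function(c_i, rcs) {
  if (rcs$degenerate) stop("degenerate tumor projections (zero MAD)")
  z <- (as.numeric(c_i) - rcs$mu_hat) / rcs$s_hat
  structure(abs(z), signed = z)
}

#' Two-sided congruence p-value for the deviance score
#'
#' Under the null \eqn{c_i = \mu_k} with tumor projections treated as
#' \eqn{N(\mu_k, \sigma)}, \eqn{p = 2(1 - \Phi(|c_i - \hat\mu_k| /
#' \hat\sigma))}. Large p signals congruence (absence of evidence for a
#' displaced model), so models are retained, not rejected, at large p.
#'
#' @inheritParams ds_sda
#' @return numeric vector of p-values in [0, 1].
#' @export
ds_pvalue <- function(c_i, rcs) {
  if (rcs$degenerate || rcs$sigma_hat == 0) stop("degenerate tumor dispersion")
  2 * stats::pnorm(-abs(as.numeric(c_i) - rcs$mu_hat) / rcs$sigma_hat)
}

#' Bootstrap confidence interval for the deviance score
#'
#' Ordinary bootstrap on the tumor projections: \code{b} resamples with
#' replacement, each yielding a recomputed median/MAD and deviance score for
#' the fixed model projection \code{c_i}; the percentile interval (R quantile
#' type 7) is taken on the log2 scale and back-transformed. Replicates with
#' zero MAD or zero deviance are dropped from the log transform with their
#' count recorded (probability ~0 for continuous projections).
#'
#' @param c_i single model projection value.
#' @param tumor_proj numeric vector of target-class tumor projections (>= 3).
#' @param b number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param mad_constant MAD consistency constant.
#' @return list: \code{ci_low}, \code{ci_high}, \code{replicates} (the kept
#'   DS replicates), \code{n_dropped}.
#' @export
bootstrap_ci <- function(c_i, tumor_proj, b = 1000L, level = 0.95, seed = 1L,
                         mad_constant = 1.4826) {
  v <- as.numeric(tumor_proj)
  n <- length(v)
  if (n < 3L) stop("need >=3 tumor projections")
  stopifnot(length(c_i) == 1L, b >= 2L, level > 0, level < 1)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = b)
  ds_b <- apply(idx, 1L, function(ii) {
    vb <- v[ii]
    mu <- stats::median(vb)
    s <- mad_constant * stats::median(abs(vb - mu))
    if (s == 0) return(NA_real_)
    abs(c_i - mu) / s
  })
  keep <- !is.na(ds_b) & ds_b > 0
  n_dropped <- sum(!keep)
  if (all(!keep)) stop("all bootstrap replicates degenerate")
  q <- stats::quantile(log2(ds_b[keep]),
                       probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 7, names = FALSE)
  list(ci_low = 2^q[1L], ci_high = 2^q[2L],
       replicates = ds_b[keep], n_dropped = n_dropped)
}

#' Gene-level deviance score
#'
#' \eqn{DS_{gene}(g,i,k) = (c_{g,i} - \hat\mu_{g,k}) / \hat\sigma_g} with
#' \eqn{\hat\mu_{g,k}} the target-class tumor median and \eqn{\hat\sigma_g}
#' its scaled MAD for gene g. Signed: positive means the model over-expresses
#' the gene relative to the tumor cohort. Genes with zero MAD get \code{NA}
#' (excluded from pathway aggregation with a logged count).
#'
#' @param model_expr numeric vector: the model's expression for each gene.
#' @param tumor_expr numeric matrix genes x tumor samples (target class only),
#'   or a vector for a single gene.
#' @param mad_constant MAD consistency constant.
#' @return numeric vector of signed deviance scores, one per gene.
#' @export
ds_gene <- function(model_expr, tumor_expr, mad_constant = 1.4826) {
  if (is.null(dim(tumor_expr)))
    tumor_expr <- matrix(tumor_expr, nrow = 1L)
  if (ncol(tumor_expr) < 3L) stop("need >=3 tumor samples per gene")
  mu <- apply(tumor_expr, 1L, stats::median)
  sg <- mad_constant * apply(abs(tumor_expr - mu), 1L, stats::median)
  out <- (as.numeric(model_expr) - mu) / sg
  out[sg == 0] <- NA_real_
  out
}

#' Pathway-level deviance score
#'
#' Geometric mean of the absolute gene-level deviance scores over the
#' pathway's differentially expressed genes: \eqn{\exp(mean(\log
#' |DS_{gene}|))}. The geometric mean damps outlier genes. \code{NA} entries
#' (zero-MAD genes) are excluded; an exact zero makes the score 0 (the limit
#' of the geometric mean).
#'
#' @param gene_devs numeric vector of signed gene-level deviance scores.
#' @return single non-negative deviance score.
#' @export
ds_path <- function(gene_devs) {
  a <- abs(gene_devs[!is.na(gene_devs)])
  if (length(a) == 0L) stop("no usable gene deviance values")
  if (any(a == 0)) return(0)
  exp(mean(log(a)))
}

#' Empirical one-sided p-value for a pathway deviance score
#'
#' The null distribution is the pathway deviance of the target-class tumor
#' samples themselves; the add-one permutation-style estimator
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + N)} avoids p = 0. Small p
#' means the model deviates more than tumors do, i.e. worse congruence.
#'
#' @param observed the model's pathway deviance score.
#' @param tumor_ds_path numeric vector of tumor null scores (see
#'   [tumor_pathway_null()]).
#' @return p-value in (0, 1].
#' @export
ds_path_pvalue <- function(observed, tumor_ds_path) {
  null <- tumor_ds_path[!is.na(tumor_ds_path)]
  if (length(null) == 0L) stop("empty null vector")
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Leave-one-out tumor null for pathway deviance
#'
#' Scores each target-class tumor sample as if it were a candidate model,
#' with itself excluded from the median/MAD computation (avoids the self-bias
#' of scoring a sample against statistics containing it).
#'
#' @param tumor_expr numeric matrix genes x target-class tumor samples
#'   (restricted to the genes to be aggregated).
#' @param pathways named list mapping pathway name to gene symbols (only
#'   genes present in \code{tumor_expr} are used).
#' @param mad_constant MAD consistency constant.
#' @return matrix pathways x tumor samples of null pathway deviance scores.
#' @export
tumor_pathway_null <- function(tumor_expr, pathways, mad_constant = 1.4826) {
  nt <- ncol(tumor_expr)
  if (nt < 4L) stop("need >=4 tumor samples for a leave-one-out null")
  out <- matrix(NA_real_, length(pathways), nt,
                dimnames = list(names(pathways), colnames(tumor_expr)))
  for (j in seq_len(nt)) {
    dg <- ds_gene(tumor_expr[, j], tumor_expr[, -j, drop = FALSE], mad_constant)
    names(dg) <- rownames(tumor_expr)
    for (p in names(pathways)) {
      g <- intersect(pathways[[p]], rownames(tumor_expr))
      if (length(g) > 0L && !all(is.na(dg[g]))) out[p, j] <- ds_path(dg[g])
    }
  }
  out
}

#' Genome-wide deviance table for candidate models
#'
#' Convenience wrapper producing one record per candidate model: projection,
#' deviance score with bootstrap CI and p-value, and assignment probability.
#'
#' @param model an [fit_sda()] model.
#' @param tumor harmonized tumor [expr_matrix()] (training cohort).
#' @param models harmonized model [expr_matrix()].
#' @param labels [sample_annotation()] covering the tumor samples.
#' @param target target class label (class k).
#' @param b,seed,level bootstrap parameters, see [bootstrap_ci()].
#' @param mad_constant,sigma_policy see [robust_center_scale()].
#' @return data frame: \code{model_id}, \code{projection}, \code{ds_sda},
#'   \code{ds_signed}, \code{ci_low}, \code{ci_high}, \code{pval},
#'   \code{p_sda}.
#' @export
deviance_table <- function(model, tumor, models, labels, target,
                           b = 1000L, seed = 1L, level = 0.95,
                           mad_constant = 1.4826,
                           sigma_policy = c("mad", "sd")) {
  sigma_policy <- match.arg(sigma_policy)
  tp <- sda_project(model, tumor)
  y <- training_labels(labels, tp$sample_id, target)
  tk <- tp$value[y == target]
  rcs <- robust_center_scale(tk, mad_constant, sigma_policy)
  mp <- sda_project(model, models)
  ds <- ds_sda(mp$value, rcs)
  ci <- lapply(seq_len(nrow(mp)), function(i)
    bootstrap_ci(mp$value[i], tk, b = b, level = level,
                 seed = seed + i - 1L, mad_constant = mad_constant))
  data.frame(model_id = mp$sample_id,
             projection = mp$value,
             ds_sda = as.numeric(ds),
             ds_signed = attr(ds, "signed"),
             ci_low = vapply(ci, `[[`, numeric(1), "ci_low"),
             ci_high = vapply(ci, `[[`, numeric(1), "ci_high"),
             pval = ds_pvalue(mp$value, rcs),
             p_sda = assignment_probability(model, mp),
             stringsAsFactors = FALSE)
}

#' Gene-level deviance matrix for candidate models
#'
#' @param tumor harmonized tumor [expr_matrix()].
#' @param models harmonized model [expr_matrix()] (same genes).
#' @param labels,target define the target-class tumor subset.
#' @param genes optional gene subset (default: all shared genes).
#' @param mad_constant MAD consistency constant.
#' @return matrix genes x models of signed gene-level deviance scores.
#' @export
gene_deviance_matrix <- function(tumor, models, labels, target,
                                 genes = NULL, mad_constant = 1.4826) {
  if (!identical(rownames(tumor), rownames(models)))
    stop("tumor and models must share gene order (run intersect_genes)")
  y <- training_labels(labels, colnames(tumor), target)
  tk <- as_plain(tumor)[, y == target, drop = FALSE]
  mm <- as_plain(models)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(tk))
    tk <- tk[genes, , drop = FALSE]; mm <- mm[genes, , drop = FALSE]
  }
  out <- sapply(seq_len(ncol(mm)), function(i) ds_gene(mm[, i], tk, mad_constant))
  out <- matrix(out, nrow = nrow(tk),
                dimnames = list(rownames(tk), colnames(mm)))
  n_zero_mad <- sum(is.na(out[, 1L]))
  if (n_zero_mad > 0L)
    warning(n_zero_mad, " gene(s) with zero tumor MAD excluded (NA)")
  out
}
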