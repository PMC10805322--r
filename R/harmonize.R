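#' Harmonization configuration
#'
#' @param method one of \code{"none"}, \code{"quantile"}, \code{"eb_batch"},
#'   \code{"cpca_mnn"}.
#' @param n_cpc_remove number of contrastive principal directions removed from
#'   each side in the cPCA step (default 4).
#' @param mnn_k neighbor count for the mutual-nearest-neighbor step (default
#'   5); 0 disables the MNN step (with \code{n_cpc_remove = 0} the aligner is
#'   a no-op).
#' @param cpca_alpha contrast weight (>= 0) in the contrastive covariance
#'   \eqn{Cov_{tumor} - \alpha\, Cov_{model}} (default 1).
#' @param seed integer seed recorded for provenance (the aligner itself is
#'   deterministic).
#' @return list of class \code{harmonization_config}.
#' @export
harmonization_config <- function(method = c("none", "quantile", "eb_batch", "cpca_mnn"),
                                 n_cpc_remove = 4L, mnn_k = 5L,
                                 cpca_alpha = 1, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_cpc_remove >= 0, mnn_k >= 0, cpca_alpha >= 0)
  structure(list(method = method, n_cpc_remove = as.integer(n_cpc_remove),
                 mnn_k = as.integer(mnn_k), cpca_alpha = cpca_alpha,
                 seed = as.integer(seed)),
            class = "harmonization_config")
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same distribution: the across-
#' column mean of order statistics. Ties within a column receive the mean of
#' their target quantile values (the interpolated-average-rank rule).
#'
#' @param x an [expr_matrix()] on the log2 scale with at least 2 samples. A
#'   single-sample matrix is returned unchanged with a warning.
#' @return quantile-normalized [expr_matrix()].
#' @export
quantile_normalize <- function(x) {
  m <- as_plain(x)
  if (ncol(m) < 2L) {
    warning("quantile normalization needs >=2 samples; returning input unchanged")
    return(x)
  }
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    out[, j] <- (ref[floor(rk)] + ref[ceiling(rk)]) / 2
  }
  expr_matrix(out, expr_scale(x))
}

#' Empirical-Bayes batch correction
#'
#' Parametric location/scale batch adjustment for known batches: per-gene
#' batch means and variances are shrunk toward common priors (normal prior on
#' the location effect, inverse-gamma on the scale effect, both estimated by
#' moments from the data) and removed, leaving the grand per-gene mean and
#' pooled variance.
#'
#' @param x an [expr_matrix()] (log2 scale).
#' @param batch character/factor vector of batch labels, one per sample; at
#'   least two batches, each with at least two samples.
#' @param max_iter,tol fixed-point control for the joint posterior solution of
#'   the location/scale effects.
#' @return batch-corrected [expr_matrix()], same shape.
#' @export
eb_batch_correct <- function(x, batch, max_iter = 100L, tol = 1e-6) {
  m <- as_plain(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(m)) stop("one batch label per sample required")
  tab <- table(batch)
  if (length(tab) < 2L) stop("need >=2 batches")
  if (any(tab < 2L)) stop("every batch needs >=2 samples, offending: ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  batches <- names(tab)
  n <- ncol(m)
  nb <- as.numeric(tab[batches])

  # standardize: grand mean weighted by batch size, pooled variance
  bmean <- sapply(batches, function(b) rowMeans(m[, batch == b, drop = FALSE]))
  grand <- as.vector(bmean %*% (nb / n))
  resid <- m - grand
  for (i in seq_along(batches))
    resid[, batch == batches[i]] <- m[, batch == batches[i]] - bmean[, i]
  pooled_var <- rowSums(resid^2) / n
  pooled_var[pooled_var == 0] <- .Machine$double.eps
  z <- (m - grand) / sqrt(pooled_var)

  out <- z
  for (i in seq_along(batches)) {
    sel <- batch == batches[i]
    zb <- z[, sel, drop = FALSE]
    ni <- sum(sel)
    g_hat <- rowMeans(zb)                       # per-gene batch location
    d_hat <- rowSums((zb - g_hat)^2) / (ni - 1) # per-gene batch scale
    # moment estimates of the priors
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    v <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + v^2) / s2
    b_prior <- (v * s2 + v^3) / s2
    # joint fixed point for posterior location/scale (standard EB adjustment)
    g_star <- g_hat; d_star <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- (ni * t2 * g_hat + d_star * g_bar) / (ni * t2 + d_star)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * ss + b_prior) / (ni / 2 + a_prior - 1)
      delta <- max(max(abs(g_new - g_star) / (abs(g_star) + 1e-12)),
                   max(abs(d_new - d_star) / (abs(d_star) + 1e-12)))
      g_star <- g_new; d_star <- d_new
      if (delta < tol) break
    }
    out[, sel] <- (zb - g_star) / sqrt(d_star)
  }
  expr_matrix(out * sqrt(pooled_var) + grand, expr_scale(x))
}

# top-k eigenvectors of a symmetric matrix
top_eigvec <- function(s, k) {
  if (k == 0L) return(matrix(0, nrow(s), 0L))
  e <- eigen(s, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE]
}

#' Contrastive-PCA plus mutual-nearest-neighbor alignment
#'
#' A simplified two-step tumor/model aligner. Step 1 removes, from both
#' matrices, the leading eigenvectors of the contrastive gene-gene covariances
#' \eqn{Cov_{tumor} - \alpha Cov_{model}} and \eqn{Cov_{model} - \alpha
#' Cov_{tumor}} (directions of variance specific to one source, e.g. normal
#' cell contamination in tumors). Step 2 finds mutual nearest neighbor pairs
#' between tumor and model samples in the residualized space and moves each
#' model sample by a kernel-smoothed average of its pairs' tumor-minus-model
#' difference vectors (tumors are the reference and are not moved in step 2).
#'
#' @param tumor,model gene-intersected [expr_matrix()] objects (same genes,
#'   same order); each must have more samples than \code{cfg$n_cpc_remove}.
#' @param cfg a [harmonization_config()].
#' @return list with elements \code{tumor} and \code{model} (aligned matrices)
#'   and \code{n_pairs} (number of mutual pairs; 0 triggers a warning and the
#'   step-1-only result).
#' @export
cpca_mnn_align <- function(tumor, model, cfg = harmonization_config("cpca_mnn")) {
  if (!identical(rownames(tumor), rownames(model)))
    stop("tumor and model must be gene-intersected first (identical gene order)")
  tm <- as_plain(tumor); mm <- as_plain(model)
  k <- cfg$n_cpc_remove
  if (ncol(tm) <= k || ncol(mm) <= k)
    stop("each side needs more samples than n_cpc_remove")

  # step 1: contrastive residualization in gene space
  ct <- stats::cov(t(tm)); cm <- stats::cov(t(mm))
  v <- cbind(top_eigvec(ct - cfg$cpca_alpha * cm, k),
             top_eigvec(cm - cfg$cpca_alpha * ct, k))
  if (ncol(v) > 0L) {
    v <- qr.Q(qr(v))     # orthonormal basis of the removed subspace
    ctr <- rowMeans(cbind(tm, mm))
    tm <- ctr + (tm - ctr) - v %*% (t(v) %*% (tm - ctr))
    mm <- ctr + (mm - ctr) - v %*% (t(v) %*% (mm - ctr))
  }

  # step 2: mutual nearest neighbors, models moved toward tumors
  kk <- cfg$mnn_k
  if (kk == 0L)
    return(list(tumor = expr_matrix(tm, expr_scale(tumor)),
                model = expr_matrix(mm, expr_scale(model)), n_pairs = 0L))
  d2 <- outer(colSums(mm^2), colSums(tm^2), "+") - 2 * crossprod(mm, tm)
  nt <- ncol(tm); nm <- ncol(mm)
  k_mt <- min(kk, nt); k_tm <- min(kk, nm)
  nn_mt <- t(apply(d2, 1L, function(r) order(r)[seq_len(k_mt)]))  # model -> tumors
  nn_tm <- t(apply(d2, 2L, function(r) order(r)[seq_len(k_tm)]))  # tumor -> models
  pairs <- NULL
  for (i in seq_len(nm)) for (j in nn_mt[i, ])
    if (i %in% nn_tm[j, ]) pairs <- rbind(pairs, c(i, j))
  if (is.null(pairs)) {
    warning("no mutual nearest neighbor pairs found; returning cPCA-only result")
    return(list(tumor = expr_matrix(tm, expr_scale(tumor)),
                model = expr_matrix(mm, expr_scale(model)), n_pairs = 0L))
  }
  diffs <- tm[, pairs[, 2L], drop = FALSE] - mm[, pairs[, 1L], drop = FALSE]
  # smooth correction vectors across model samples (Gaussian kernel on the
  # model-model distances; bandwidth = median distance, keeps nearby models
  # moving coherently instead of collapsing each onto its matched tumors)
  dmm2 <- outer(colSums(mm^2), colSums(mm^2), "+") - 2 * crossprod(mm)
  dmm2[dmm2 < 0] <- 0
  # wide bandwidth (3x the median inter-model distance): the batch vector is
  # assumed smooth, so nearby models share a correction instead of each being
  # pulled onto its own matched tumors, which would absorb the very
  # displacement the deviance scores measure
  sigma2 <- 9 * stats::median(dmm2[dmm2 > 0])
  if (!is.finite(sigma2) || sigma2 == 0) sigma2 <- 1
  w <- exp(-dmm2[, pairs[, 1L], drop = FALSE] / sigma2)   # nm x npairs
  corr <- diffs %*% t(w / rowSums(w))                     # genes x nm
  mm <- mm + corr
  list(tumor = expr_matrix(tm, expr_scale(tumor)),
       model = expr_matrix(mm, expr_scale(model)),
       n_pairs = nrow(pairs))
}

#' Harmonize tumor and model expression
#'
#' Dispatches to the configured method and records it in a provenance
#' attribute. \code{"quantile"} normalizes tumor and model columns jointly;
#' \code{"eb_batch"} treats tumor and model as the two batches;
#' \code{"cpca_mnn"} runs [cpca_mnn_align()]; \code{"none"} is a pass-through
#' (use it when supplying matrices already aligned by an external tool).
#'
#' @param tumor,model gene-intersected [expr_matrix()] objects.
#' @param cfg a [harmonization_config()].
#' @return list with \code{tumor}, \code{model}, and \code{provenance}.
#' @export
harmonize <- function(tumor, model, cfg = harmonization_config("none")) {
  if (!inherits(cfg, "harmonization_config")) stop("cfg must be a harmonization_config")
  if (!identical(rownames(tumor), rownames(model)))
    stop("run intersect_genes() before harmonize()")
  res <- switch(cfg$method,
    none = list(tumor = tumor, model = model),
    quantile = {
      joint <- quantile_normalize(expr_matrix(cbind(as_plain(tumor), as_plain(model)),
                                              expr_scale(tumor)))
      list(tumor = expr_matrix(as_plain(joint)[, colnames(tumor), drop = FALSE],
                               expr_scale(tumor)),
           model = expr_matrix(as_plain(joint)[, colnames(model), drop = FALSE],
                               expr_scale(model)))
    },
    eb_batch = {
      joint <- eb_batch_correct(
        expr_matrix(cbind(as_plain(tumor), as_plain(model)), expr_scale(tumor)),
        batch = rep(c("tumor", "model"), c(ncol(tumor), ncol(model))))
      list(tumor = expr_matrix(as_plain(joint)[, colnames(tumor), drop = FALSE],
                               expr_scale(tumor)),
           model = expr_matrix(as_plain(joint)[, colnames(model), drop = FALSE],
                               expr_scale(model)))
    },
    cpca_mnn = cpca_mnn_align(tumor, model, cfg)[c("tumor", "model")],
    stop("unknown harmonization method: ", cfg$method))
  res$provenance <- unclass(cfg)
  res
}
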