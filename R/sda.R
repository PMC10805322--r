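#' Fit sparse discriminant analysis by penalized optimal scoring
#'
#' Linear discriminant analysis recast as a regression problem: with
#' \eqn{Y} the n x 2 class indicator matrix and \eqn{X} the standardized
#' samples x genes matrix, solve
#' \deqn{\min_{\theta,\beta} \|Y\theta - X\beta\|^2 + \gamma \beta^T\beta +
#'       \lambda \|\beta\|_1 \quad s.t.\ \tfrac1n \theta^T Y^T Y \theta = 1,}
#' alternating an elastic-net regression for \eqn{\beta} given the optimal
#' scores \eqn{\theta} with the exact constrained score update given
#' \eqn{\beta}. The lasso weight \eqn{\lambda} makes \eqn{\beta} sparse, so the
#' fitted discriminant axis is interpretable as a gene signature. Genes are
#' centered and unit-variance scaled internally (constant genes dropped with a
#' warning); the centering/scaling is stored and re-applied at projection time,
#' so rescaling the input leaves the classifier unchanged.
#'
#' @param x tumor [expr_matrix()] (genes x samples, log2 scale).
#' @param labels either a [sample_annotation()] covering the samples of
#'   \code{x} or a vector of two-level class labels in column order.
#' @param target the label of the target subtype (class k). Defaults to the
#'   first level encountered.
#' @param gamma ridge weight (>= 0).
#' @param lam lasso weight (>= 0), or \code{NULL} when \code{nnz} is given.
#' @param nnz alternative sparsity control: largest model with at most
#'   \code{nnz} nonzero coefficients on the glmnet path is used at each
#'   beta-step.
#' @param max_iter,tol alternation control; convergence is declared when the
#'   relative objective decrease falls below \code{tol}.
#' @param priors \code{"observed"} (class proportions, the default; tumor
#'   cohorts are typically imbalanced) or \code{"equal"} for the 1-D LDA on
#'   the projected axis.
#' @param seed seed for the random initial score vector.
#' @return an object of class \code{sda_model}: \code{beta} (named sparse
#'   coefficient vector over genes), \code{theta}, \code{selected_genes},
#'   \code{center}/\code{scale}, \code{objective} (per-iteration trace),
#'   \code{lda1d} (class means/medians, pooled sd, priors on the projected
#'   axis), \code{class_names} (target first), and the tuning parameters.
#' @export
fit_sda <- function(x, labels, target = NULL, gamma = 1e-3, lam = 1e-2,
                    nnz = NULL, max_iter = 50L, tol = 1e-8,
                    priors = c("observed", "equal"), seed = 1L) {
  priors <- match.arg(priors)
  xm <- t(as_plain(x))                       # samples x genes
  if (inherits(labels, "sample_annotation") || is.data.frame(labels)) {
    if (is.null(target)) {
      lab0 <- labels$class_label[match(rownames(xm), labels$sample_id)]
      target <- lab0[!is.na(lab0)][1L]
    }
    y <- training_labels(labels, rownames(xm), target)
  } else {
    lab <- as.character(labels)
    if (length(lab) != nrow(xm)) stop("one label per sample required")
    lev <- unique(lab)
    if (length(lev) != 2L) stop("exactly two class labels required, got: ",
                                paste(lev, collapse = ", "))
    if (is.null(target)) target <- lev[1L]
    y <- factor(lab, levels = c(target, setdiff(lev, target)))
  }
  n <- nrow(xm)
  nk <- table(y)
  if (any(nk < 2L)) stop("each class needs >=2 samples")
  if (is.null(lam) && is.null(nnz)) stop("supply lam or nnz")
  stopifnot(gamma >= 0, is.null(lam) || lam >= 0)

  ctr <- colMeans(xm)
  scl <- apply(xm, 2L, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant gene(s) dropped before SDA fit")
    xm <- xm[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
  }
  xs <- sweep(sweep(xm, 2L, ctr), 2L, scl, "/")
  genes <- colnames(xs)
  ymat <- cbind(as.numeric(y == levels(y)[1L]), as.numeric(y == levels(y)[2L]))
  d <- as.numeric(nk[levels(y)]) / n         # (1/n) Y'Y diagonal

  norm_theta <- function(th) {
    th <- th - sum(d * th)                   # remove the trivial constant score
    th / sqrt(sum(d * th^2))
  }
  set.seed(seed)
  theta <- norm_theta(stats::rnorm(2L))
  obj <- function(th, b) {
    r <- ymat %*% th - xs %*% b
    sum(r^2) + gamma * sum(b^2) + if (is.null(lam)) 0 else lam * sum(abs(b))
  }
  beta <- rep(0, ncol(xs))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ystar <- as.vector(ymat %*% theta)
    beta <- solve_enet(xs, ystar, gamma, lam, nnz, n)
    if (all(beta == 0)) stop("all coefficients shrunk to zero; decrease lam")
    theta <- norm_theta(as.vector(crossprod(ymat, xs %*% beta)) / (n * d))
    trace <- c(trace, obj(theta, beta))
    if (it > 1L && abs(trace[it - 1L] - trace[it]) <=
          tol * max(1, abs(trace[it - 1L]))) break
  }
  if (it == max_iter && (length(trace) < 2L ||
      abs(trace[it - 1L] - trace[it]) > tol * max(1, abs(trace[it - 1L]))))
    warning("SDA alternation did not reach tol in ", max_iter, " iterations")

  proj <- as.vector(xs %*% beta)
  # orient the axis so the target class sits on the positive side
  if (mean(proj[y == levels(y)[1L]]) < mean(proj[y == levels(y)[2L]])) {
    beta <- -beta; theta <- -theta; proj <- -proj
  }
  pri <- if (priors == "observed") as.numeric(nk[levels(y)]) / n else c(0.5, 0.5)
  mu <- tapply(proj, y, mean)
  pooled_sd <- sqrt(sum(tapply(proj, y, function(v) sum((v - mean(v))^2))) /
                    (n - 2L))
  if (pooled_sd == 0) stop("degenerate pooled variance on the projected axis")
  names(beta) <- genes
  structure(list(
    beta = beta, theta = theta, gamma = gamma, lam = lam, nnz = nnz,
    selected_genes = genes[beta != 0],
    center = ctr, scale = scl, genes = genes,
    class_names = levels(y),
    objective = trace, iterations = it,
    train_projection = stats::setNames(proj, rownames(xm)),
    lda1d = list(means = as.numeric(mu[levels(y)]),
                 medians = as.numeric(tapply(proj, y, stats::median)[levels(y)]),
                 pooled_sd = pooled_sd, priors = pri)),
    class = "sda_model")
}

# elastic net solve of ystar on xs for the optimal-scoring beta step.
# Objective ||ystar - xs b||^2 + gamma||b||^2 + lam||b||_1, mapped onto
# glmnet's (1/2n)RSS + lambda_g[(1-a)/2 ||b||^2 + a ||b||_1] scaling.
solve_enet <- function(xs, ystar, gamma, lam, nnz, n) {
  if (!is.null(nnz)) {
    fit <- glmnet::glmnet(xs, ystar, alpha = 1, standardize = FALSE,
                          intercept = FALSE, dfmax = max(nnz + 1L, 2L))
    ok <- which(fit$df <= nnz & fit$df > 0L)
    if (length(ok) == 0L) ok <- length(fit$df)
    as.vector(fit$beta[, max(ok)])
  } else if (lam > 0) {
    a <- lam / (lam + 2 * gamma)
    lg <- (lam + 2 * gamma) / (2 * n)
    fit <- glmnet::glmnet(xs, ystar, alpha = a, lambda = lg,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    as.vector(fit$beta[, 1L])
  } else {
    # pure ridge (closed form); gamma may be 0 on full-rank data
    g <- ncol(xs)
    as.vector(solve(crossprod(xs) + diag(gamma, g), crossprod(xs, ystar)))
  }
}

#' @export
print.sda_model <- function(x, ...) {
  cat(sprintf("sda_model: %s vs %s, %d/%d genes selected, %d iterations\n",
              x$class_names[1L], x$class_names[2L],
              length(x$selected_genes), length(x$genes), x$iterations))
  invisible(x)
}

#' Project samples onto the fitted discriminant axis
#'
#' Applies the training-time centering/scaling and the sparse discriminant
#' vector: \eqn{c_i = \tilde x_i^T \beta}. The input must cover all selected
#' genes; genes absent from the model are ignored, genes with zero weight may
#' be absent from the input.
#'
#' @param model an [fit_sda()] model.
#' @param x an [expr_matrix()] (genes x samples) on the same harmonized scale
#'   as the training data.
#' @return data frame with columns \code{sample_id} and \code{value}.
#' @export
sda_project <- function(model, x) {
  m <- as_plain(x)
  if (all(model$genes %in% rownames(m))) use <- model$genes
  else {
    missing <- setdiff(model$selected_genes, rownames(m))
    if (length(missing) > 0L)
      stop("selected genes missing from input: ", paste(missing, collapse = ", "))
    use <- model$selected_genes
  }
  idx <- match(use, model$genes)
  xs <- (t(m[use, , drop = FALSE]) -
           matrix(model$center[idx], ncol(m), length(use), byrow = TRUE)) /
        matrix(model$scale[idx], ncol(m), length(use), byrow = TRUE)
  data.frame(sample_id = colnames(m),
             value = as.vector(xs %*% model$beta[idx]),
             stringsAsFactors = FALSE)
}

#' Assignment probability on the projected axis
#'
#' Posterior probability of the target class from the one-dimensional
#' Gaussian LDA fitted on the tumor projections (equal class variances, priors
#' as configured at fit time).
#'
#' @param model an [fit_sda()] model.
#' @param proj numeric vector of projection values or the data frame returned
#'   by [sda_project()].
#' @return numeric vector of probabilities for the target class, in [0, 1].
#' @export
assignment_probability <- function(model, proj) {
  v <- if (is.data.frame(proj)) proj$value else as.numeric(proj)
  l <- model$lda1d
  lk <- stats::dnorm(v, l$means[1L], l$pooled_sd) * l$priors[1L]
  lo <- stats::dnorm(v, l$means[2L], l$pooled_sd) * l$priors[2L]
  # log-space fallback for far tails where both densities underflow
  p <- lk / (lk + lo)
  far <- !is.finite(p) | (lk + lo) == 0
  if (any(far)) {
    a <- stats::dnorm(v[far], l$means[1L], l$pooled_sd, log = TRUE) + log(l$priors[1L])
    b <- stats::dnorm(v[far], l$means[2L], l$pooled_sd, log = TRUE) + log(l$priors[2L])
    p[far] <- 1 / (1 + exp(b - a))
  }
  p
}

#' Cross-validated tuning of the SDA penalties
#'
#' Repeated stratified k-fold cross-validation over a (gamma, lambda) grid;
#' accuracy is the proportion of held-out tumor samples assigned to their true
#' class (posterior threshold 0.5). Ties are broken toward sparser models
#' (larger lambda), then larger gamma.
#'
#' @param x,labels,target as in [fit_sda()].
#' @param gamma_grid,lam_grid numeric grids (non-empty).
#' @param folds number of folds (>= 2, and at most the smaller class size).
#' @param repeats number of random fold repartitions.
#' @param seed integer seed controlling the fold assignments.
#' @return list with \code{gamma}, \code{lam}, and \code{accuracy} (the full
#'   grid with mean CV accuracy and the per-cell nonzero count of a full-data
#'   refit).
#' @export
cv_tune_sda <- function(x, labels, target = NULL,
                        gamma_grid = 10^c(-3, -1), lam_grid = 10^seq(-3, 0, by = 1),
                        folds = 5L, repeats = 1L, seed = 1L) {
  if (length(gamma_grid) == 0L || length(lam_grid) == 0L) stop("empty tuning grid")
  xm <- as_plain(x)
  if (inherits(labels, "sample_annotation") || is.data.frame(labels)) {
    if (is.null(target)) {
      lab0 <- labels$class_label[match(colnames(xm), labels$sample_id)]
      target <- lab0[!is.na(lab0)][1L]
    }
    y <- training_labels(labels, colnames(xm), target)
  } else {
    lev <- unique(as.character(labels))
    if (is.null(target)) target <- lev[1L]
    y <- factor(as.character(labels), levels = c(target, setdiff(lev, target)))
  }
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > min(table(y))) stop("fold count exceeds the smaller class size")

  grid <- expand.grid(gamma = gamma_grid, lam = lam_grid)
  acc <- matrix(NA_real_, nrow(grid), repeats)
  set.seed(seed)
  for (r in seq_len(repeats)) {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    hits <- matrix(0, nrow(grid), 2L)  # correct, total
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      xtr <- expr_matrix(xm[, tr, drop = FALSE], expr_scale(x))
      xte <- expr_matrix(xm[, te, drop = FALSE], expr_scale(x))
      for (gcell in seq_len(nrow(grid))) {
        fit <- tryCatch(
          fit_sda(xtr, as.character(y)[tr], target = levels(y)[1L],
                  gamma = grid$gamma[gcell], lam = grid$lam[gcell],
                  seed = seed),
          error = function(e) NULL)
        if (is.null(fit)) next
        p <- assignment_probability(fit, sda_project(fit, xte))
        pred <- ifelse(p > 0.5, levels(y)[1L], levels(y)[2L])
        hits[gcell, ] <- hits[gcell, ] + c(sum(pred == as.character(y)[te]), sum(te))
      }
    }
    acc[, r] <- hits[, 1L] / hits[, 2L]
  }
  grid$accuracy <- rowMeans(acc)
  # tie-breaks: max accuracy, then larger lam (sparser), then larger gamma
  ord <- order(-grid$accuracy, -grid$lam, -grid$gamma)
  best <- grid[ord[1L], ]
  list(gamma = best$gamma, lam = best$lam, accuracy = grid)
}
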