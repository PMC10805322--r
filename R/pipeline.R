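#' Model pre-selection criteria
#'
#' Thresholds for the genome-wide pre-selection stage. All comparisons are
#' strict inequalities: a model passes the base rule when its target-class
#' assignment probability exceeds \code{p_sda_min} AND its deviance p-value
#' exceeds \code{ds_pval_min} (large p = no evidence of displacement =
#' congruent); the stringent rule tightens both. Pinned models are carried
#' forward regardless.
#'
#' @param p_sda_min,ds_pval_min base thresholds (defaults 0.5, 0.05).
#' @param stringent_p_sda_min,stringent_ds_pval_min stringent thresholds
#'   (defaults 0.8, 0.1); must not be below the base thresholds.
#' @param pinned_models,pinned_pathways character vectors of user-pinned
#'   entities.
#' @return list of class \code{selection_criteria}.
#' @export
selection_criteria <- function(p_sda_min = 0.5, ds_pval_min = 0.05,
                               stringent_p_sda_min = 0.8,
                               stringent_ds_pval_min = 0.1,
                               pinned_models = character(0),
                               pinned_pathways = character(0)) {
  stopifnot(p_sda_min >= 0, p_sda_min <= 1, ds_pval_min >= 0, ds_pval_min <= 1,
            stringent_p_sda_min >= p_sda_min,
            stringent_ds_pval_min >= ds_pval_min,
            stringent_p_sda_min <= 1, stringent_ds_pval_min <= 1)
  structure(list(p_sda_min = p_sda_min, ds_pval_min = ds_pval_min,
                 stringent_p_sda_min = stringent_p_sda_min,
                 stringent_ds_pval_min = stringent_ds_pval_min,
                 pinned_models = as.character(pinned_models),
                 pinned_pathways = as.character(pinned_pathways)),
            class = "selection_criteria")
}

#' Flag candidate models against the pre-selection criteria
#'
#' @param dev deviance table from [deviance_table()].
#' @param crit a [selection_criteria()].
#' @param stage which flag defines \code{selected}: \code{"stringent"}
#'   (default, mirrors the final pre-selection) or \code{"base"}.
#' @return the deviance table with added logical columns \code{base_pass},
#'   \code{stringent_pass}, \code{pinned}, \code{selected}.
#' @export
preselect_models <- function(dev, crit = selection_criteria(),
                             stage = c("stringent", "base")) {
  stage <- match.arg(stage)
  dev$base_pass <- dev$p_sda > crit$p_sda_min & dev$pval > crit$ds_pval_min
  dev$stringent_pass <- dev$p_sda > crit$stringent_p_sda_min &
    dev$pval > crit$stringent_ds_pval_min
  dev$pinned <- dev$model_id %in% crit$pinned_models
  dev$selected <- (if (stage == "stringent") dev$stringent_pass else
    dev$base_pass) | dev$pinned
  dev
}

#' Pathway-level deviance scores for pre-selected models
#'
#' For every (pathway, model) pair: the geometric-mean deviance over the
#' pathway's DE genes and its one-sided empirical p-value against the
#' leave-one-out tumor null, with the p-value glyph bin used by the heatmap
#' rendering (1: p < 0.1, 2: p < 0.05, 3: p < 0.01; larger = worse
#' congruence).
#'
#' @param tumor,models harmonized [expr_matrix()] objects (same genes);
#'   \code{models} restricted to the pre-selected candidates.
#' @param labels,target define the target-class tumor subset.
#' @param de DE table ([differential_expression()] or external).
#' @param pathways named list of gene sets to score (typically the selection
#'   set plus pins from [filter_pathways()]).
#' @param mad_constant MAD consistency constant.
#' @return data frame: \code{pathway}, \code{model_id}, \code{ds_path},
#'   \code{pval}, \code{n_genes_used}, \code{glyph}.
#' @export
score_pathways <- function(tumor, models, labels, target, de, pathways,
                           mad_constant = 1.4826) {
  de <- as_de_result(de)
  de_genes <- de$gene[de$is_de]
  path_de <- lapply(pathways, function(g)
    intersect(intersect(g, de_genes), rownames(tumor)))
  empty <- lengths(path_de) == 0L
  if (any(empty))
    stop("pathway(s) with zero usable DE genes: ",
         paste(names(pathways)[empty], collapse = ", "))
  dg <- gene_deviance_matrix(tumor, models, labels, target,
                             genes = unique(unlist(path_de)),
                             mad_constant = mad_constant)
  y <- training_labels(labels, colnames(tumor), target)
  tk <- as_plain(tumor)[rownames(dg), y == target, drop = FALSE]
  null <- tumor_pathway_null(tk, path_de, mad_constant)
  out <- do.call(rbind, lapply(names(path_de), function(p) {
    vals <- vapply(colnames(dg), function(m) ds_path(dg[path_de[[p]], m]),
                   numeric(1))
    pv <- vapply(vals, ds_path_pvalue, numeric(1), tumor_ds_path = null[p, ])
    data.frame(pathway = p, model_id = colnames(dg), ds_path = vals, pval = pv,
               n_genes_used = length(path_de[[p]]),
               glyph = findInterval(-pv, c(-Inf, -0.1, -0.05, -0.01)) - 1L,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Final pathway-aware model ranking
#'
#' Ascending order of the arithmetic mean pathway deviance over the unbiased
#' selection pathways (pinned pathways are excluded from the average); ties
#' broken by the genome-wide deviance score, then by model id.
#'
#' @param path_scores output of [score_pathways()].
#' @param selection_pathways character vector of pathway names entering the
#'   average (the non-pinned selection set).
#' @param dev deviance table providing \code{ds_sda} for tie-breaks.
#' @return data frame ordered by rank: \code{model_id}, \code{avg_ds_path},
#'   \code{ds_sda}, \code{rank}.
#' @export
rank_models <- function(path_scores, selection_pathways, dev) {
  sub <- path_scores[path_scores$pathway %in% selection_pathways, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no pathway scores on the selection set")
  models <- sort(unique(path_scores$model_id))
  miss <- vapply(models, function(m)
    any(!selection_pathways %in% sub$pathway[sub$model_id == m]), logical(1))
  if (any(miss)) stop("missing pathway scores for: ",
                      paste(models[miss], collapse = ", "))
  avg <- tapply(sub$ds_path, sub$model_id, mean)
  ds <- dev$ds_sda[match(names(avg), dev$model_id)]
  ord <- order(avg, ds, names(avg))
  data.frame(model_id = names(avg)[ord],
             avg_ds_path = as.numeric(avg)[ord],
             ds_sda = ds[ord],
             rank = seq_along(ord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()]. Every source of
#' randomness derives from \code{seed}, so a config plus seed fully determines
#' the report.
#'
#' @param target target subtype label.
#' @param harmonize a [harmonization_config()].
#' @param sda list: \code{gamma}, \code{lam} (\code{"cv"} to tune by
#'   cross-validation), \code{priors}, and when tuning \code{gamma_grid},
#'   \code{lam_grid}, \code{folds}, \code{repeats}. The defaults (gamma = 100,
#'   lam = 5, on the raw residual-sum-of-squares scale of the objective) are
#'   sized for a cohort of a few hundred samples over a few hundred genes:
#'   under-penalized optimal scoring with more genes than samples interpolates
#'   the class scores, which collapses the within-class projection spread and
#'   wildly inflates every deviance score. Retune (e.g. \code{lam = "cv"}) for
#'   other problem sizes.
#' @param deviance list: \code{b} (bootstrap replicates), \code{mad_constant},
#'   \code{sigma_policy}.
#' @param de list: \code{method}, \code{fc_threshold}, \code{alpha}; supply
#'   \code{external} (a DE data frame) to inject e.g. DESeq2 output.
#' @param gsea list: \code{n_perm}, \code{weight_p}, \code{min_size}.
#' @param filters list: \code{min_de}, \code{size_low}, \code{size_high},
#'   \code{nes_abs}.
#' @param selection a [selection_criteria()].
#' @param seed master seed.
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(target,
                            harmonize = harmonization_config("none"),
                            sda = list(gamma = 100, lam = 5,
                                       priors = "observed"),
                            deviance = list(b = 1000L, mad_constant = 1.4826,
                                            sigma_policy = "mad"),
                            de = list(method = "welch_log",
                                      fc_threshold = 1.5, alpha = 0.05),
                            gsea = list(n_perm = 2000L, weight_p = 1,
                                        min_size = 3L),
                            filters = list(min_de = 20L, size_low = 30L,
                                           size_high = 200L, nes_abs = 1.5),
                            selection = selection_criteria(),
                            seed = 1L) {
  structure(list(target = target, harmonize = harmonize, sda = sda,
                 deviance = deviance, de = de, gsea = gsea, filters = filters,
                 selection = selection, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full congruence-and-selection pipeline
#'
#' Orchestrates harmonization, discriminant fitting, genome-wide deviance and
#' pre-selection, differential expression, enrichment, pathway filtering,
#' pathway-level scoring and final ranking. When \code{out_dir} is given,
#' every stage's table is written as TSV plus a \code{report.json} carrying
#' the configuration, seed and package version; identical config + seed gives
#' a byte-identical report.
#'
#' @param tumor,models [expr_matrix()] objects (or TSV paths accepted by
#'   [read_expression()]).
#' @param annotation [sample_annotation()] (or a TSV path).
#' @param pathways named gene-set list (or a GMT path).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class \code{congruence_report}: \code{deviance} (with
#'   pre-selection flags), \code{de}, \code{gsea}, \code{pathway_filters},
#'   \code{pathway_scores}, \code{ranking} (NULL when no pathway survives and
#'   nothing is pinned, with a warning), \code{provenance}.
#' @export
run_pipeline <- function(tumor, models, annotation, pathways, config,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(tumor)) tumor <- read_expression(tumor)
  if (is.character(models)) models <- read_expression(models)
  if (is.character(annotation)) annotation <- read_sample_annotation(annotation)
  if (is.character(pathways)) pathways <- read_gmt(pathways)

  shared <- intersect_genes(tumor, models)
  harm <- harmonize(shared$a, shared$b, config$harmonize)
  tum <- harm$tumor; mod <- harm$model

  sda_cfg <- config$sda
  if (identical(sda_cfg$lam, "cv")) {
    tuned <- cv_tune_sda(tum, annotation, target = config$target,
                         gamma_grid = sda_cfg$gamma_grid %||% 10^c(-3, -1),
                         lam_grid = sda_cfg$lam_grid %||% 10^seq(-3, 0),
                         folds = sda_cfg$folds %||% 5L,
                         repeats = sda_cfg$repeats %||% 1L,
                         seed = config$seed)
    sda_cfg$gamma <- tuned$gamma; sda_cfg$lam <- tuned$lam
  }
  fit <- fit_sda(tum, annotation, target = config$target,
                 gamma = sda_cfg$gamma %||% 1e-3, lam = sda_cfg$lam,
                 priors = sda_cfg$priors %||% "observed", seed = config$seed)

  devc <- config$deviance
  dev <- deviance_table(fit, tum, mod, annotation, config$target,
                        b = devc$b %||% 1000L, seed = config$seed,
                        mad_constant = devc$mad_constant %||% 1.4826,
                        sigma_policy = devc$sigma_policy %||% "mad")
  dev <- preselect_models(dev, config$selection)

  dec <- config$de
  de <- if (!is.null(dec$external)) {
    as_de_result(dec$external, dec$fc_threshold %||% 1.5, dec$alpha %||% 0.05)
  } else {
    differential_expression(tum, annotation, target = config$target,
                            method = dec$method %||% "welch_log",
                            fc_threshold = dec$fc_threshold %||% 1.5,
                            alpha = dec$alpha %||% 0.05)
  }
  ranks <- stats::setNames(de$log2fc, de$gene)
  ranks <- ranks[!is.na(ranks)]
  gc <- config$gsea
  enr <- preranked_gsea(ranks, pathways, n_perm = gc$n_perm %||% 2000L,
                        weight_p = gc$weight_p %||% 1,
                        min_size = gc$min_size %||% 3L, seed = config$seed)
  fl <- config$filters
  filt <- filter_pathways(enr, de, pathways,
                          min_de = fl$min_de %||% 20L,
                          size_low = fl$size_low %||% 30L,
                          size_high = fl$size_high %||% 200L,
                          nes_abs = fl$nes_abs %||% 1.5,
                          pinned = config$selection$pinned_pathways)

  sel_models <- dev$model_id[dev$selected]
  path_scores <- NULL; ranking <- NULL
  if (nrow(filt$selection) == 0L) {
    warning("no pathway passed the filters and none pinned; ",
            "report contains the genome-wide ranking only")
  } else if (length(sel_models) == 0L) {
    warning("no model passed pre-selection and none pinned; ",
            "report contains the genome-wide table only")
  } else {
    mod_sel <- expr_matrix(as_plain(mod)[, sel_models, drop = FALSE],
                           expr_scale(mod))
    path_scores <- score_pathways(tum, mod_sel, annotation, config$target, de,
                                  pathways[filt$selection$pathway],
                                  mad_constant = devc$mad_constant %||% 1.4826)
    unpinned <- filt$selection$pathway[!filt$selection$pinned]
    ranking <- if (length(unpinned) > 0L)
      rank_models(path_scores, unpinned, dev)
    else {
      warning("only pinned pathways available; ranking uses them")
      rank_models(path_scores, filt$selection$pathway, dev)
    }
  }

  report <- structure(list(
    deviance = dev, de = de, gsea = enr,
    pathway_filters = filt, pathway_scores = path_scores, ranking = ranking,
    provenance = list(package = "modelcongr",
                      version = as.character(utils::packageVersion("modelcongr")),
                      seed = config$seed,
                      target = config$target,
                      config = serializable_config(config))),
    class = "congruence_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wt(dev, "deviance.tsv"); wt(de, "de.tsv"); wt(enr, "gsea.tsv")
    wt(path_scores, "pathway_deviance.tsv"); wt(ranking, "ranking.tsv")
    jsonlite::write_json(unclass_recursive(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  report
}

# strip S3 classes so jsonlite serializes plainly and reproducibly
unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x), stringsAsFactors = FALSE))
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  if (is.matrix(x)) return(x)
  unclass(x)
}

serializable_config <- function(cfg) {
  out <- unclass_recursive(cfg)
  # external DE tables can be large; record a fingerprint, not the table
  if (!is.null(out$de$external))
    out$de$external <- paste0("external table, ", nrow(cfg$de$external), " genes")
  out
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("congruence_report\n")
  cat(sprintf("  models evaluated: %d (%d pre-selected)\n",
              nrow(x$deviance), sum(x$deviance$selected)))
  cat(sprintf("  DE genes: %d; pathways scored: %d\n",
              sum(x$de$is_de),
              if (is.null(x$pathway_scores)) 0L
              else length(unique(x$pathway_scores$pathway))))
  if (!is.null(x$ranking)) {
    cat("  ranking (avg pathway deviance, ascending):\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}
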