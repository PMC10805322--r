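#' Construct a validated expression matrix
#'
#' The shared container for all expression data in the package: a genes x
#' samples numeric matrix with unique gene symbols as row names, unique sample
#' identifiers as column names, and a declared value scale. Expression on the
#' \code{"log2tpm"} scale is the working currency of every downstream statistic;
#' \code{"counts"} matrices (non-negative integers) are accepted only as input
#' to the negative-binomial differential-expression backend.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique and non-empty.
#' @param scale either \code{"log2tpm"} or \code{"counts"}.
#' @return An object of class \code{expr_matrix}: the matrix itself with the
#'   scale stored in attribute \code{"scale"}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' x <- expr_matrix(m)
#' expr_scale(x)
#' @export
expr_matrix <- function(values, scale = c("log2tpm", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || any(!nzchar(gid)))
    stop("gene ids (row names) must be present and non-empty")
  if (is.null(sid) || any(!nzchar(sid)))
    stop("sample ids (column names) must be present and non-empty")
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not allowed in a validated expression matrix")
  if (scale == "counts" && (any(values < 0) || any(values != round(values))))
    stop("scale=\"counts\" requires non-negative integer entries")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an \code{expr_matrix}.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "log2tpm"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# strip class/attributes for plain numeric work (dimnames kept)
as_plain <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- NULL
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  x
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated UTF-8 file with a header row of sample identifiers
#' and gene symbols in the first column (the GEO/DepMap genes-in-rows
#' convention); \code{transpose = TRUE} handles the other orientation.
#'
#' @param path file path.
#' @param scale declared value scale, see [expr_matrix()].
#' @param missing_policy what to do with missing cells: \code{"error"}
#'   (default; silent imputation could corrupt deviance scores),
#'   \code{"drop_gene"} (remove genes with any missing entry), or
#'   \code{"zero"} (replace by 0).
#' @param dup_policy what to do with duplicated gene rows: \code{"error"}
#'   (default) or \code{"first"} (keep the first occurrence).
#' @param transpose set TRUE when the file has samples in rows.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, scale = c("log2tpm", "counts"),
                            missing_policy = c("error", "drop_gene", "zero"),
                            dup_policy = c("error", "first"),
                            transpose = FALSE) {
  scale <- match.arg(scale)
  missing_policy <- match.arg(missing_policy)
  dup_policy <- match.arg(dup_policy)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed expression TSV: need gene column plus >=1 sample")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    # columns with any non-numeric token are read as character
    stop("non-numeric cells in sample column(s): ",
         paste(colnames(vals)[bad], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    if (dup_policy == "error")
      stop("duplicated gene rows: ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
  }
  if (anyNA(m)) {
    if (missing_policy == "error") {
      stop("missing cells in expression matrix (missing_policy=\"error\")")
    } else if (missing_policy == "drop_gene") {
      keep <- rowSums(is.na(m)) == 0L
      m <- m[keep, , drop = FALSE]
      if (nrow(m) == 0L) stop("all genes dropped by missing_policy=\"drop_gene\"")
    } else {
      m[is.na(m)] <- 0
    }
  }
  expr_matrix(m, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()] up to float formatting at the declared
#' precision; \code{read_expression(write_expression(x))} round-trips a
#' validated matrix.
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @param digits significant digits written (default 15, enough for an exact
#'   double round trip in practice).
#' @export
write_expression <- function(x, path, digits = 15) {
  m <- as_plain(x)
  df <- data.frame(gene = rownames(m),
                   signif(m, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' GMT dialect: one set per line, \code{name TAB description TAB gene1 TAB
#' gene2 ...}. Gene symbols are whitespace-trimmed and de-duplicated within
#' each set.
#'
#' @param path file path.
#' @return a named list of character vectors with a \code{"description"}
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (fewer than 3 fields): ", substr(ln, 1, 60))
    nm <- trimws(f[1L])
    if (nm %in% names(sets)) stop("duplicate pathway name in GMT: ", nm)
    genes <- unique(trimws(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("empty gene set in GMT: ", nm)
    sets[[nm]] <- genes
    desc[nm] <- trimws(f[2L])
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors (see [read_gmt()]).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Sample annotation table
#'
#' Validates a per-sample annotation data frame. Columns: \code{sample_id},
#' \code{source} (\code{"tumor"} or \code{"model"}), and \code{class_label}
#' (subtype label; required for tumor samples used in training, where exactly
#' two distinct labels must be present). Extra columns are carried through
#' untouched.
#'
#' @param df data frame with at least \code{sample_id} and \code{source}.
#' @return the validated data frame (classes \code{sample_annotation},
#'   \code{data.frame}).
#' @export
sample_annotation <- function(df) {
  if (!all(c("sample_id", "source") %in% names(df)))
    stop("annotation needs columns sample_id and source")
  df$sample_id <- as.character(df$sample_id)
  df$source <- as.character(df$source)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  if (!all(df$source %in% c("tumor", "model")))
    stop("source must be \"tumor\" or \"model\"")
  if (is.null(df$class_label)) df$class_label <- NA_character_
  df$class_label <- as.character(df$class_label)
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' @rdname sample_annotation
#' @param path TSV file with a header.
#' @export
read_sample_annotation <- function(path) {
  sample_annotation(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

# binary class labels for the tumor training samples; first element = target
training_labels <- function(ann, sample_ids, target) {
  ann <- ann[match(sample_ids, ann$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("samples missing from annotation")
  lab <- ann$class_label
  if (anyNA(lab) | any(!nzchar(lab)))
    stop("every tumor training sample needs a class_label")
  lev <- unique(lab)
  if (length(lev) != 2L)
    stop("training labels must take exactly two values, got: ",
         paste(lev, collapse = ", "))
  if (!target %in% lev) stop("target class \"", target, "\" not among labels")
  factor(lab, levels = c(target, setdiff(lev, target)))
}

#' Restrict two expression matrices to their common genes
#'
#' @param a,b validated [expr_matrix()] objects.
#' @return list with elements \code{a} and \code{b}, both restricted to the
#'   gene intersection in identical order (order of appearance in \code{a}).
#' @export
intersect_genes <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0L) stop("no genes in common between the two matrices")
  list(a = expr_matrix(as_plain(a)[common, , drop = FALSE], expr_scale(a)),
       b = expr_matrix(as_plain(b)[common, , drop = FALSE], expr_scale(b)))
}
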