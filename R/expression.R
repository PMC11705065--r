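#' Expression matrix with gene and sample annotations
#'
#' The central container of the pipeline: a numeric matrix of log2-scale
#' expression values (genes in rows, samples in columns) together with a
#' per-gene class label and, in cell-line mode, per-sample condition and
#' cell-line-pair labels.
#'
#' Three modes are supported:
#' \describe{
#'   \item{cellline}{paired resistant/sensitive cell-line profiles; every
#'     sample carries a `condition` (`"resistant"` or `"sensitive"`) and a
#'     `pair_id` identifying its cell-line pair.}
#'   \item{cohort}{bulk tumor cohort; no condition/pair annotations.}
#'   \item{panel}{cell-line panel (e.g. for drug-activity correlation); no
#'     condition/pair annotations.}
#' }
#'
#' @param values numeric matrix, genes x samples, finite, log2 scale.
#'   Must have unique, non-empty rownames (gene ids) and colnames (sample
#'   ids).
#' @param gene_class character vector, one of `"lncRNA"`, `"miRNA"`,
#'   `"mRNA"` per gene. A single value is recycled.
#' @param mode one of `"cellline"`, `"cohort"`, `"panel"`.
#' @param sample_condition character vector (`"resistant"`/`"sensitive"`)
#'   per sample; required in cellline mode, must be absent otherwise.
#' @param pair_id character vector of cell-line-pair labels per sample;
#'   required in cellline mode.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `gene_class`, `mode`, `sample_condition`, `pair_id`.
#' @export
expr_matrix <- function(values, gene_class,
                        mode = c("cellline", "cohort", "panel"),
                        sample_condition = NULL, pair_id = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (!all(is.finite(values))) stop("`values` must be finite")
  gene_class <- as.character(gene_class)
  if (length(gene_class) == 1L) {
    gene_class <- rep(gene_class, nrow(values))
  }
  if (length(gene_class) != nrow(values)) {
    stop("`gene_class` must have one entry per gene")
  }
  bad <- setdiff(unique(gene_class), c("lncRNA", "miRNA", "mRNA"))
  if (length(bad)) stop("unknown gene_class: ", paste(bad, collapse = ", "))
  names(gene_class) <- rownames(values)

  if (mode == "cellline") {
    if (is.null(sample_condition) || is.null(pair_id)) {
      stop("cellline mode requires `sample_condition` and `pair_id`")
    }
    sample_condition <- as.character(sample_condition)
    pair_id <- as.character(pair_id)
    if (length(sample_condition) != ncol(values) ||
        length(pair_id) != ncol(values)) {
      stop("`sample_condition` and `pair_id` must have one entry per sample")
    }
    badc <- setdiff(unique(sample_condition), c("resistant", "sensitive"))
    if (length(badc)) {
      stop("unknown sample_condition: ", paste(badc, collapse = ", "))
    }
    names(sample_condition) <- colnames(values)
    names(pair_id) <- colnames(values)
  } else {
    if (!is.null(sample_condition) || !is.null(pair_id)) {
      stop("sample_condition/pair_id are only valid in cellline mode")
    }
  }

  structure(
    list(values = values, gene_class = gene_class, mode = mode,
         sample_condition = sample_condition, pair_id = pair_id),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(table(x$gene_class)),
                    table(x$gene_class)), collapse = ", "), "\n")
  if (x$mode == "cellline") {
    cat("  pairs:", paste(unique(x$pair_id), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

collapse_duplicate_genes <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  # mean across rows sharing a gene id; first-appearance order preserved
  out <- rowsum(values, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out[unique(ids), , drop = FALSE]
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids. Gene and sample annotations come from
#' side-car tables (or in-memory data frames) rather than overloaded
#' headers, keeping the matrix file a plain genes x samples TSV.
#'
#' Rows sharing a gene id are collapsed to their mean, the convention for
#' multiple probes mapping to one gene. The result is order-independent:
#' permuting input rows yields the same matrix up to first-appearance row
#' order.
#'
#' @param path path to the matrix TSV.
#' @param mode `"cellline"`, `"cohort"`, or `"panel"`.
#' @param gene_class either a single class label applied to all genes, or a
#'   data frame / path to a two-column TSV (`gene_id`, `gene_class`).
#' @param sample_annotation data frame or path to a TSV with columns
#'   `sample_id`, `condition`, `pair_id`; required in cellline mode.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` on ingest (for
#'   raw-TPM inputs); internal representation is always log2 scale.
#' @return [expr_matrix()]
#' @export
read_expression <- function(path, mode = c("cellline", "cohort", "panel"),
                            gene_class = "mRNA", sample_annotation = NULL,
                            log2_transform = FALSE) {
  mode <- match.arg(mode)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("no records in ", path)
  ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, sample_ids))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d (gene '%s'), column '%s'",
                 bad[["row"]], ids[bad[["row"]]], sample_ids[bad[["col"]]]))
  }
  rownames(num) <- ids
  num <- collapse_duplicate_genes(num)
  if (log2_transform) num <- log2(num + 1)

  if (is.character(gene_class) && length(gene_class) == 1L &&
      file.exists(gene_class)) {
    gene_class <- utils::read.delim(gene_class, sep = "\t",
                                    colClasses = "character")
  }
  if (is.data.frame(gene_class)) {
    gc <- gene_class$gene_class[match(rownames(num), gene_class$gene_id)]
    if (anyNA(gc)) {
      stop("genes missing from gene_class annotation: ",
           paste(utils::head(rownames(num)[is.na(gc)], 5L), collapse = ", "))
    }
    gene_class <- gc
  }

  cond <- pair <- NULL
  if (mode == "cellline") {
    if (is.null(sample_annotation)) {
      stop("cellline mode requires `sample_annotation`")
    }
    if (is.character(sample_annotation)) {
      sample_annotation <- utils::read.delim(sample_annotation, sep = "\t",
                                             colClasses = "character")
    }
    m <- match(colnames(num), sample_annotation$sample_id)
    if (anyNA(m)) {
      stop("samples missing from annotation: ",
           paste(colnames(num)[is.na(m)], collapse = ", "))
    }
    cond <- sample_annotation$condition[m]
    pair <- sample_annotation$pair_id[m]
  }
  expr_matrix(num, gene_class, mode = mode,
              sample_condition = cond, pair_id = pair)
}

#' Write an expression matrix (and its annotations) to TSV
#'
#' @param em [expr_matrix()]
#' @param path matrix TSV path (first column `gene_id`).
#' @param gene_annotation_path optional path for the gene side-car TSV.
#' @param sample_annotation_path optional path for the sample side-car TSV
#'   (cellline mode).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, gene_annotation_path = NULL,
                             sample_annotation_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gene_annotation_path)) {
    utils::write.table(
      data.frame(gene_id = rownames(em$values), gene_class = em$gene_class),
      gene_annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sample_annotation_path) && em$mode == "cellline") {
    utils::write.table(
      data.frame(sample_id = colnames(em$values),
                 condition = em$sample_condition, pair_id = em$pair_id),
      sample_annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param em [expr_matrix()]
#' @param genes,samples character vectors of ids to keep (default all).
#' @return [expr_matrix()]
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (is.null(genes)) genes <- rownames(em$values)
  if (is.null(samples)) samples <- colnames(em$values)
  missing_g <- setdiff(genes, rownames(em$values))
  if (length(missing_g)) {
    stop("genes not present: ", paste(missing_g, collapse = ", "))
  }
  v <- em$values[genes, samples, drop = FALSE]
  expr_matrix(v, em$gene_class[genes], mode = em$mode,
              sample_condition = em$sample_condition[samples],
              pair_id = em$pair_id[samples])
}
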