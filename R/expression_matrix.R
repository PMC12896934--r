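#' Expression matrix with sample-group assignments
#'
#' Container for a genes x samples expression matrix in a two-parent/hybrid
#' design. Each sample belongs to exactly one of the groups `"parentA"`,
#' `"parentB"` or `"hybrid"`, and the matrix carries a scale tag recording
#' whether values are raw counts, normalized abundance (FPKM/CPM-like), or
#' log2 abundance.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param groups Character vector or factor assigning each sample to one of
#'   `"parentA"`, `"parentB"`, `"hybrid"`. Either named by sample id or given
#'   in column order.
#' @param scale One of `"counts"`, `"abundance"`, `"log2_abundance"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (numeric matrix), `groups` (factor named by sample id) and
#'   `scale`.
#' @export
expression_matrix <- function(values,
                              groups,
                              scale = c("counts", "abundance", "log2_abundance")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_usage("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_usage("'values' must have gene ids as rownames and sample ids as colnames")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop_format("duplicate gene id(s): %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop_format("duplicate sample id(s): %s", paste(dup_s, collapse = ", "))
  }
  samples <- colnames(values)
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing <- setdiff(samples, names(groups))
    if (length(missing)) {
      stop_format("sample(s) not assigned to a group: %s",
                  paste(missing, collapse = ", "))
    }
    groups <- groups[samples]
  } else if (length(groups) == length(samples)) {
    names(groups) <- samples
  } else {
    stop_usage("'groups' must be named by sample id or match the number of columns")
  }
  bad <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(bad)) {
    stop_format("unknown group label(s): %s (expected %s)",
                paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = "/"))
  }
  groups <- factor(groups, levels = GROUP_LEVELS)
  empty <- GROUP_LEVELS[!GROUP_LEVELS %in% groups]
  if (length(empty)) {
    stop_format("group(s) with no samples: %s", paste(empty, collapse = ", "))
  }
  if (scale != "log2_abundance" && any(!is.finite(values) | values < 0)) {
    stop_format("values must be finite and non-negative on the %s scale", scale)
  }
  if (scale == "log2_abundance" && any(!is.finite(values))) {
    stop_format("values must be finite")
  }
  structure(list(values = values, groups = groups, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  samples/group:",
      paste(sprintf("%s=%d", levels(x$groups), table(x$groups)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Per-group mean expression
#'
#' Arithmetic mean of each gene's expression within each sample group, on the
#' matrix's current scale.
#'
#' @param expr An [expression_matrix()].
#' @return Numeric matrix, genes x groups (`parentA`, `parentB`, `hybrid`).
#' @export
group_means <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  out <- vapply(GROUP_LEVELS, function(g) {
    rowMeans(expr$values[, expr$groups == g, drop = FALSE])
  }, numeric(nrow(expr$values)))
  # vapply drops to a vector for a single gene; keep the matrix contract
  if (!is.matrix(out)) {
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(expr$values), GROUP_LEVELS))
  }
  out
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is TSV with a header row, gene ids in the first column and
#' one column per sample. The sample sheet is TSV with columns `sample_id`
#' and `group` (values `parentA`/`parentB`/`hybrid`). Comment lines starting
#' with `#` and trailing blank lines are tolerated in both files.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV.
#' @param scale Scale tag of the stored values (default `"counts"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, sample_sheet_path, scale = "counts") {
  if (!file.exists(matrix_path)) stop_usage("file not found: %s", matrix_path)
  if (!file.exists(sample_sheet_path)) stop_usage("file not found: %s", sample_sheet_path)
  tab <- utils::read.delim(matrix_path, check.names = FALSE, comment.char = "#",
                           blank.lines.skip = TRUE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop_format("duplicate gene id(s) in %s: %s", matrix_path,
                paste(dup, collapse = ", "))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids

  sheet <- read_sample_sheet(sample_sheet_path)
  missing <- setdiff(colnames(values), sheet$sample_id)
  if (length(missing)) {
    stop_format("sample(s) in matrix but not in sample sheet: %s",
                paste(missing, collapse = ", "))
  }
  extra <- setdiff(sheet$sample_id, colnames(values))
  if (length(extra)) {
    stop_format("sample(s) in sheet but absent from matrix: %s",
                paste(extra, collapse = ", "))
  }
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  expression_matrix(values, groups, scale = scale)
}

#' Read a sample sheet
#'
#' @param path TSV file with columns `sample_id` and `group`.
#' @return data.frame with character columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, comment.char = "#", blank.lines.skip = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(sheet))) {
    stop_format("sample sheet %s must have columns: %s", path,
                paste(need, collapse = ", "))
  }
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup)) {
    stop_format("duplicate sample id(s) in sheet: %s", paste(dup, collapse = ", "))
  }
  sheet[, need]
}

#' Write an expression matrix and sample sheet to TSV
#'
#' Values are serialized at full double precision so that a write/read
#' round-trip reproduces them to at least 6 significant digits.
#'
#' @param expr An [expression_matrix()].
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, matrix_path, sample_sheet_path = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  if (!is.null(sample_sheet_path)) {
    sheet <- data.frame(sample_id = names(expr$groups),
                        group = as.character(expr$groups),
                        stringsAsFactors = FALSE)
    write_tsv(sheet, sample_sheet_path)
  }
  invisible(expr)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' FPKM normalization of a count matrix
#'
#' Computes `count * 1e9 / (gene_length * column_total)` per cell: fragments
#' per kilobase of transcript per million mapped reads. When no lengths are
#' supplied every gene is treated as 1 kb, which reduces to counts per
#' million (CPM); per-gene statistics downstream are invariant to the gene
#' length, so this fallback only changes the absolute scale.
#'
#' @param expr An [expression_matrix()] on the counts scale.
#' @param gene_lengths Named numeric vector of transcript lengths in bases,
#'   covering every gene in `expr`; `NULL` for the CPM fallback.
#' @return An [expression_matrix()] on the abundance scale.
#' @export
normalize_fpkm <- function(expr, gene_lengths = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "counts") stop_usage("normalize_fpkm expects a counts matrix")
  genes <- rownames(expr$values)
  if (is.null(gene_lengths)) {
    warning("no gene lengths supplied; using 1 kb for every gene (CPM fallback)")
    len <- rep(1000, length(genes))
  } else {
    missing <- setdiff(genes, names(gene_lengths))
    if (length(missing)) {
      stop_lookup("no length for gene(s): %s",
                  paste(utils::head(missing, 5), collapse = ", "))
    }
    len <- as.numeric(gene_lengths[genes])
    if (any(!is.finite(len) | len <= 0)) stop_usage("gene lengths must be positive")
  }
  totals <- colSums(expr$values)
  if (any(totals == 0)) {
    stop_format("zero library size in sample(s): %s",
                paste(colnames(expr$values)[totals == 0], collapse = ", "))
  }
  vals <- sweep(expr$values * 1e9 / len, 2, totals, "/")
  expression_matrix(vals, expr$groups, scale = "abundance")
}

#' Ratio-based size factors
#'
#' Robust per-sample scaling factors from the distribution of each sample's
#' count ratios against the per-gene geometric-mean reference (genes with
#' nonzero counts in every sample). Unlike raw library totals these are
#' insensitive to a minority of strongly regulated genes (composition
#' bias). The default summarizes each sample's log-ratios by their
#' kernel-density mode, which stays anchored on the unregulated bulk of the
#' transcriptome even when the regulated fractions are large and
#' asymmetric (as when a fifth of genes are transgressively up in the
#' hybrid); `method = "median"` gives the classical median-of-ratios.
#'
#' @param expr An [expression_matrix()] on the counts scale.
#' @param method `"mode"` (default) or `"median"` summary of the log-ratios.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
estimate_size_factors <- function(expr, method = c("mode", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "counts") stop_usage("estimate_size_factors expects counts")
  logc <- log(expr$values)
  ref <- rowMeans(logc)
  use <- is.finite(ref)
  if (!any(use)) stop_format("no gene has nonzero counts in every sample")
  logratio <- logc[use, , drop = FALSE] - ref[use]
  centre <- switch(method,
    median = function(x) stats::median(x),
    mode = function(x) {
      if (length(x) < 10 || stats::sd(x) == 0) return(stats::median(x))
      d <- stats::density(x, n = 512)
      d$x[which.max(d$y)]
    })
  sf <- exp(apply(logratio, 2, centre))
  sf / exp(mean(log(sf)))
}

#' Size-factor based abundance normalization
#'
#' FPKM-like normalization with the per-sample divisor taken as
#' `size_factor * geometric-mean library total` instead of the sample's own
#' raw total: `count * 1e9 / (length * size_factor * geomean_total)`. With
#' `method = "total_count"` this reduces to [normalize_fpkm()]. The
#' median-of-ratios default is robust to composition bias from large
#' transgressive gene classes.
#'
#' @param expr An [expression_matrix()] on the counts scale.
#' @param gene_lengths Optional named lengths in bases (1 kb fallback).
#' @param method `"median_ratios"` (default) or `"total_count"`.
#' @return An [expression_matrix()] on the abundance scale.
#' @export
normalize_abundance <- function(expr, gene_lengths = NULL,
                                method = c("median_ratios", "total_count")) {
  method <- match.arg(method)
  if (method == "total_count") return(normalize_fpkm(expr, gene_lengths))
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "counts") stop_usage("normalize_abundance expects counts")
  genes <- rownames(expr$values)
  if (is.null(gene_lengths)) {
    len <- rep(1000, length(genes))
  } else {
    missing <- setdiff(genes, names(gene_lengths))
    if (length(missing)) {
      stop_lookup("no length for gene(s): %s",
                  paste(utils::head(missing, 5), collapse = ", "))
    }
    len <- as.numeric(gene_lengths[genes])
    if (any(!is.finite(len) | len <= 0)) stop_usage("gene lengths must be positive")
  }
  totals <- colSums(expr$values)
  if (any(totals == 0)) {
    stop_format("zero library size in sample(s): %s",
                paste(colnames(expr$values)[totals == 0], collapse = ", "))
  }
  lib <- estimate_size_factors(expr) * exp(mean(log(totals)))
  vals <- sweep(expr$values * 1e9 / len, 2, lib, "/")
  expression_matrix(vals, expr$groups, scale = "abundance")
}

#' Log2 transform of an abundance matrix
#'
#' @param expr An [expression_matrix()] on the abundance scale.
#' @param pseudocount Positive value added before taking log2 (default 1).
#' @return An [expression_matrix()] on the log2_abundance scale.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "abundance") {
    stop_usage("log_transform expects an abundance-scale matrix, got '%s'", expr$scale)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_usage("pseudocount must be positive")
  }
  expression_matrix(log2(expr$values + pseudocount), expr$groups,
                    scale = "log2_abundance")
}
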