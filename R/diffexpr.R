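#' Differential-expression thresholds
#'
#' Defaults follow the common volcano convention for this design: raw
#' p < 0.05 and |log2 fold change| > 1. `use_adjusted = TRUE` switches the
#' significance gate to the Benjamini-Hochberg adjusted p-value.
#'
#' @param p_cutoff Significance cutoff in (0, 1).
#' @param lfc_cutoff Non-negative |log2FC| cutoff (strict inequality).
#' @param use_adjusted Gate on adjusted rather than raw p-values.
#' @return A `DEGThresholds` list.
#' @export
deg_thresholds <- function(p_cutoff = 0.05, lfc_cutoff = 1, use_adjusted = FALSE) {
  if (p_cutoff <= 0 || p_cutoff >= 1) stop_config("p_cutoff must be in (0, 1)")
  if (lfc_cutoff < 0) stop_config("lfc_cutoff must be >= 0")
  structure(list(p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "DEGThresholds")
}

# Two-sided exact rank-based p for two constant but unequal groups: every
# permutation placing all of one group's (tied, extreme) values together.
constant_unequal_p <- function(n1, n2) min(1, 2 / choose(n1 + n2, n1))

# Row-wise Welch t-test on two matrices of log2 values. Returns p-values.
welch_rows <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0   # both groups constant
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    p[equal] <- 1
    p[degenerate & !equal] <- constant_unequal_p(n1, n2)
  }
  p
}

#' Test one gene between two replicate groups
#'
#' Log2 fold change is `log2((mean_test + c) / (mean_ref + c))` on the
#' abundance scale with pseudocount `c`; the p-value comes from Welch's
#' two-sample t-test on `log2(value + c)`. When both groups are constant the
#' t statistic is undefined: equal constants give p = 1, unequal constants
#' fall back to a two-sided exact rank p (`2 / choose(n1+n2, n1)`).
#'
#' @param values_ref,values_test Numeric replicate vectors (abundance scale,
#'   at least 2 values each).
#' @param pseudocount Positive pseudocount shared with [log_transform()].
#' @return List with `log2fc` and `p_value`.
#' @export
test_gene <- function(values_ref, values_test, pseudocount = 1) {
  if (length(values_ref) < 2 || length(values_test) < 2) {
    stop_usage("need >= 2 replicates per group")
  }
  lfc <- log2((mean(values_test) + pseudocount) / (mean(values_ref) + pseudocount))
  p <- welch_rows(matrix(log2(values_ref + pseudocount), 1),
                  matrix(log2(values_test + pseudocount), 1))
  list(log2fc = lfc, p_value = as.numeric(p))
}

#' Per-gene differential expression for one pairwise contrast
#'
#' Tests every gene between two sample groups on `log2(abundance + c)`.
#' The default engine is the limma moderated t-test (`lmFit`/`eBayes`),
#' which borrows variance information across genes and is the standard
#' choice at ~5 replicates per group; `method = "welch"` uses gene-wise
#' Welch t-tests instead. Either way the reported `log2fc` is
#' `log2((mean_test + c)/(mean_ref + c))` of the group mean abundances, and
#' Benjamini-Hochberg adjusted p-values are computed over all tested genes.
#'
#' @param expr An [expression_matrix()] on the abundance scale.
#' @param reference,test Group labels; `test` up means higher in `test`.
#' @param thresholds A [deg_thresholds()].
#' @param method `"moderated"` (default) or `"welch"`.
#' @param pseudocount Positive pseudocount (default 1).
#' @return data.frame with one row per gene: `gene_id`, `reference`, `test`,
#'   `log2fc`, `p_value`, `p_adjusted`, `call` (one of `up_in_test`,
#'   `down_in_test`, `not_significant`).
#' @export
run_contrast <- function(expr, reference, test,
                         thresholds = deg_thresholds(),
                         method = c("moderated", "welch"),
                         pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(thresholds, "DEGThresholds"))
  method <- match.arg(method)
  if (expr$scale != "abundance") {
    stop_usage("run_contrast expects an abundance-scale matrix, got '%s'", expr$scale)
  }
  for (g in c(reference, test)) {
    if (!g %in% levels(expr$groups)) stop_usage("unknown group name: %s", g)
  }
  A <- expr$values[, expr$groups == reference, drop = FALSE]
  B <- expr$values[, expr$groups == test, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop_usage("need >= 2 replicates per group")

  lfc <- log2((rowMeans(B) + pseudocount) / (rowMeans(A) + pseudocount))
  LA <- log2(A + pseudocount)
  LB <- log2(B + pseudocount)
  p <- switch(method,
    welch = welch_rows(LA, LB),
    moderated = {
      y <- cbind(LA, LB)
      design <- cbind(Intercept = 1, testvsref = rep(c(0, 1), c(ncol(A), ncol(B))))
      fit <- limma::eBayes(limma::lmFit(y, design))
      pv <- fit$p.value[, "testvsref"]
      # a gene constant in both groups with zero moderated variance
      pv[is.na(pv)] <- 1
      pv
    })
  p_adj <- stats::p.adjust(p, method = "BH")
  p_use <- if (thresholds$use_adjusted) p_adj else p
  sig <- p_use < thresholds$p_cutoff
  call <- rep("not_significant", length(p))
  call[sig & lfc > thresholds$lfc_cutoff] <- "up_in_test"
  call[sig & lfc < -thresholds$lfc_cutoff] <- "down_in_test"
  data.frame(gene_id = rownames(expr$values),
             reference = reference,
             test = test,
             log2fc = as.numeric(lfc),
             p_value = as.numeric(p),
             p_adjusted = as.numeric(p_adj),
             call = call,
             stringsAsFactors = FALSE)
}

#' Filter lowly expressed genes
#'
#' Retains genes whose mean abundance across all samples is at least
#' `min_mean_abundance`; the number removed is reported via `message()`.
#'
#' @param expr An [expression_matrix()] on the abundance scale.
#' @param min_mean_abundance Non-negative threshold (default 1).
#' @return A filtered [expression_matrix()].
#' @export
filter_expressed <- function(expr, min_mean_abundance = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "abundance") {
    stop_usage("filter_expressed expects an abundance-scale matrix")
  }
  keep <- rowMeans(expr$values) >= min_mean_abundance
  message(sprintf("filter_expressed: kept %d/%d genes (mean abundance >= %g)",
                  sum(keep), length(keep), min_mean_abundance))
  if (!any(keep)) stop_usage("no genes pass the expression filter")
  expression_matrix(expr$values[keep, , drop = FALSE], expr$groups, expr$scale)
}
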