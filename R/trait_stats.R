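#' Tukey HSD comparison of one trait across groups
#'
#' One-way ANOVA supplies the pooled mean-square error; pairwise p-values
#' use the studentized range with the Tukey-Kramer adjustment for unequal
#' group sizes: `q = |m_i - m_j| / sqrt((MSE/2)(1/n_i + 1/n_j))`, referred
#' to the studentized-range distribution with `k` means and `N - k` degrees
#' of freedom. Compact letters are assigned by insert-and-absorb so that two
#' groups share a letter if and only if their adjusted p is >= alpha.
#'
#' @param values Numeric vector of trait values.
#' @param groups Factor or character vector of group labels, same length.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `TukeyResult`: `means` (named), `n` (named),
#'   `pairwise` (data.frame `group1`, `group2`, `diff`, `p_adj`),
#'   `letters` (named character), `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(as.character(groups)[ok])
  n <- tapply(values, groups, length)
  if (nlevels(groups) < 2) stop_usage("need >= 2 groups")
  if (any(n < 2)) {
    stop_usage("group(s) with < 2 observations: %s",
               paste(names(n)[n < 2], collapse = ", "))
  }
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2))) / (N - k)

  pairs <- utils::combn(levels(groups), 2)
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  q <- abs(diff) / se
  p_adj <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  p_adj[se == 0 & abs(diff) == 0] <- 1   # all-identical degenerate case
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         diff = as.numeric(diff), p_adj = as.numeric(p_adj),
                         stringsAsFactors = FALSE)
  letters <- cld_letters(levels(groups),
                         pairwise[pairwise$p_adj < alpha, c("group1", "group2"),
                                  drop = FALSE])
  structure(list(means = means, n = n, pairwise = pairwise,
                 letters = letters, alpha = alpha),
            class = "TukeyResult")
}

# Compact letter display via insert-and-absorb: start from one column
# holding every group; for each significantly different pair, split every
# column containing both; absorb columns that are subsets of others. Groups
# then share a letter iff they share a column iff they are not significantly
# different (sound and complete for the given pair list).
cld_letters <- function(groups, sig_pairs) {
  columns <- list(groups)
  for (i in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$group1[i]; g2 <- sig_pairs$group2[i]
    new_cols <- list()
    for (col in columns) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop empty columns and strict/duplicate subsets
    new_cols <- Filter(length, new_cols)
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[b] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    columns <- new_cols[keep]
  }
  labels <- letters[seq_along(columns)]
  out <- vapply(groups, function(g) {
    paste(labels[vapply(columns, function(col) g %in% col, TRUE)], collapse = "")
  }, "")
  stats::setNames(out, groups)
}

#' @export
print.TukeyResult <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g)\n", x$alpha))
  print(data.frame(mean = as.numeric(x$means), n = as.integer(x$n),
                   letters = x$letters[names(x$means)],
                   row.names = names(x$means)))
  invisible(x)
}

#' Pearson correlation between gene expression and traits
#'
#' For every requested gene and every numeric trait column, computes the
#' Pearson correlation and its two-sided p-value over the samples shared
#' between the expression matrix and the trait table. Expression enters on
#' the log2 scale by default (more robust for skewed abundances).
#' Significance stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param expr An [expression_matrix()] (abundance or log2 scale).
#' @param traits Trait table (`sample_id`, `group`, numeric traits).
#' @param genes Gene ids to correlate (default: all genes in `expr`).
#' @param use_log Log2-transform abundance values first (default TRUE).
#' @param pseudocount Pseudocount for the log transform.
#' @param adjust Apply Benjamini-Hochberg across all cells (off by default;
#'   stars then use the adjusted p).
#' @return data.frame with `gene_id`, `trait`, `n`, `r`, `p_value`, `stars`.
#'   Constant gene or trait vectors give `NA` r/p with empty stars.
#' @export
correlate_genes_traits <- function(expr, traits, genes = NULL,
                                   use_log = TRUE, pseudocount = 1,
                                   adjust = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  traits <- validate_trait_table(traits)
  genes <- genes %||% rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) {
    stop_lookup("gene(s) not in expression matrix: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  shared <- intersect(names(expr$groups), traits$sample_id)
  if (length(shared) < 3) stop_usage("need >= 3 shared samples, got %d", length(shared))
  vals <- expr$values[genes, shared, drop = FALSE]
  if (use_log && expr$scale == "abundance") vals <- log2(vals + pseudocount)
  trait_names <- setdiff(names(traits), c("sample_id", "group"))
  trow <- traits[match(shared, traits$sample_id), , drop = FALSE]

  out <- expand.grid(gene_id = genes, trait = trait_names,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- length(shared)
  res <- mapply(function(g, tr) {
    x <- vals[g, ]
    y <- trow[[tr]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(c(NA_real_, NA_real_, sum(ok)))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    c(unname(ct$estimate), ct$p.value, sum(ok))
  }, out$gene_id, out$trait)
  out$n <- as.integer(res[3, ])
  out$r <- res[1, ]
  out$p_value <- res[2, ]
  p_star <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
  if (adjust) out$p_adjusted <- p_star
  out$stars <- star_codes(p_star)
  out
}

star_codes <- function(p) {
  s <- rep("", length(p))
  s[!is.na(p) & p < 0.05] <- "*"
  s[!is.na(p) & p < 0.01] <- "**"
  s[!is.na(p) & p < 0.001] <- "***"
  s
}

#' Group trait means with compact letters
#'
#' One row per trait and group: the arithmetic group mean annotated with the
#' [tukey_hsd()] letter at the chosen alpha.
#'
#' @param traits Trait table (`sample_id`, `group`, numeric traits).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with `trait`, `group`, `mean`, `sd`, `n`, `letters`.
#' @export
summarize_traits <- function(traits, alpha = 0.05) {
  traits <- validate_trait_table(traits)
  trait_names <- setdiff(names(traits), c("sample_id", "group"))
  rows <- lapply(trait_names, function(tr) {
    th <- tukey_hsd(traits[[tr]], traits$group, alpha = alpha)
    sds <- tapply(traits[[tr]], traits$group, stats::sd)
    data.frame(trait = tr, group = names(th$means),
               mean = as.numeric(th$means),
               sd = as.numeric(sds[names(th$means)]),
               n = as.integer(th$n),
               letters = th$letters[names(th$means)],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
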