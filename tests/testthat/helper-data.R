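# Small deterministic fixtures built in code.

# Expression matrix from a genes x 3 matrix of group means (columns
# parentA, parentB, hybrid), replicated n_reps times per group with
# multiplicative lognormal noise (sd on the log scale).
toy_expr <- function(means, n_reps = 3, noise_sd = 0, scale = "abundance",
                     seed = 42) {
  means <- as.matrix(means)
  colnames(means) <- c("parentA", "parentB", "hybrid")
  if (is.null(rownames(means))) {
    rownames(means) <- sprintf("g%02d", seq_len(nrow(means)))
  }
  set.seed(seed)
  vals <- do.call(cbind, lapply(c("parentA", "parentB", "hybrid"), function(g) {
    m <- matrix(rep(means[, g], n_reps), nrow = nrow(means))
    if (noise_sd > 0) m <- m * exp(matrix(rnorm(length(m), 0, noise_sd), nrow(m)))
    colnames(m) <- sprintf("%s_%d", g, seq_len(n_reps))
    m
  }))
  rownames(vals) <- rownames(means)
  groups <- setNames(rep(c("parentA", "parentB", "hybrid"), each = n_reps),
                     colnames(vals))
  expression_matrix(vals, groups, scale = scale)
}

# Hand-built DEG record table for classifier tests.
toy_deg <- function(gene_id, call, reference, test = "hybrid") {
  data.frame(gene_id = gene_id, reference = reference, test = test,
             log2fc = ifelse(call == "up_in_test", 2,
                             ifelse(call == "down_in_test", -2, 0)),
             p_value = ifelse(call == "not_significant", 0.5, 0.001),
             p_adjusted = ifelse(call == "not_significant", 0.8, 0.01),
             call = call, stringsAsFactors = FALSE)
}
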