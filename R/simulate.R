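INHERITANCE_MODES <- c("additive", "dominant_high", "dominant_low",
                       "overdominant", "underdominant", "null")

#' Simulation configuration for a two-parent/hybrid expression experiment
#'
#' The generator emulates the design of a three-breed muscle transcriptome
#' study: two parental lines and their F1 cross, a handful of biological
#' replicates per group, and gene-wise negative-binomial counts whose group
#' means follow a chosen inheritance mode.
#'
#' @param n_genes Number of genes (default 20000).
#' @param n_reps_per_group Biological replicates per group (default 5, >= 2).
#' @param mode_fractions Named proportions over the inheritance modes
#'   `additive`, `dominant_high`, `dominant_low`, `overdominant`,
#'   `underdominant`, `null`; must sum to 1.
#' @param effect_size Multiplicative transgressive deviation (> 1): the
#'   overdominant hybrid mean is `effect_size * max(parents)` and the
#'   underdominant mean `min(parents) / effect_size`.
#' @param dispersion Negative-binomial dispersion; variance =
#'   `mu + dispersion * mu^2`. Zero gives the Poisson limit.
#' @param libsize_range Min/max multiplicative library-size factor per sample.
#' @param parent_fold Fold-difference between the parental means of non-null
#'   genes (direction randomized per gene).
#' @param base_range Range of the log-uniform baseline parental mean.
#' @param seed Integer seed; identical configurations give bit-identical data.
#' @return A `SimConfig` list (validated).
#' @export
sim_config <- function(n_genes = 20000,
                       n_reps_per_group = 5,
                       mode_fractions = c(additive = 0.15, dominant_high = 0.10,
                                          dominant_low = 0.05, overdominant = 0.20,
                                          underdominant = 0.10, null = 0.40),
                       effect_size = 2,
                       dispersion = 0.1,
                       libsize_range = c(0.7, 1.3),
                       parent_fold = 2,
                       base_range = c(20, 2000),
                       seed = 1L) {
  if (n_genes < 1) stop_config("n_genes must be positive")
  if (n_reps_per_group < 2) stop_config("n_reps_per_group must be >= 2")
  bad <- setdiff(names(mode_fractions), INHERITANCE_MODES)
  if (length(bad)) stop_config("unknown inheritance mode(s): %s", paste(bad, collapse = ", "))
  fr <- stats::setNames(rep(0, length(INHERITANCE_MODES)), INHERITANCE_MODES)
  fr[names(mode_fractions)] <- mode_fractions
  if (any(fr < 0)) stop_config("mode fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_config("mode_fractions must sum to 1 (got %.12f)", sum(fr))
  }
  if (effect_size <= 1) stop_config("effect_size must be > 1")
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  if (length(libsize_range) != 2 || libsize_range[1] <= 0 ||
      libsize_range[1] > libsize_range[2]) {
    stop_config("libsize_range must be (min, max) with 0 < min <= max")
  }
  if (parent_fold < 1) stop_config("parent_fold must be >= 1")
  if (length(base_range) != 2 || base_range[1] <= 0 || base_range[1] > base_range[2]) {
    stop_config("base_range must be (min, max) with 0 < min <= max")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_group = as.integer(n_reps_per_group),
                 mode_fractions = fr,
                 effect_size = effect_size,
                 dispersion = dispersion,
                 libsize_range = libsize_range,
                 parent_fold = parent_fold,
                 base_range = base_range,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Largest-remainder apportionment: realized mode counts match the configured
# fractions up to integer rounding and always sum to n.
mode_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Simulate a two-parent/hybrid count matrix with known inheritance modes
#'
#' Baseline parental means are drawn log-uniformly over
#' `config$base_range`; for non-null genes one parent (chosen at random) is
#' `parent_fold` times the other. The hybrid mean follows the gene's mode:
#' mid-parent for additive, the higher/lower parental mean for
#' dominant_high/dominant_low, and `effect_size` beyond the parental range
#' for the transgressive modes. Counts are negative-binomial around the mean
#' scaled by a per-sample library factor.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (counts [expression_matrix()]) and `truth`
#'   (data.frame: `gene_id`, `mode`, `mu_parentA`, `mu_parentB`, `mu_hybrid`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  counts_per_mode <- mode_counts(config$mode_fractions, n)
  mode <- rep(names(counts_per_mode), counts_per_mode)
  gene_id <- sprintf("gene%05d", seq_len(n))

  mu_a <- exp(stats::runif(n, log(config$base_range[1]), log(config$base_range[2])))
  b_higher <- stats::runif(n) < 0.5
  mu_b <- ifelse(b_higher, mu_a * config$parent_fold, mu_a / config$parent_fold)
  mu_b[mode == "null"] <- mu_a[mode == "null"]

  hi <- pmax(mu_a, mu_b)
  lo <- pmin(mu_a, mu_b)
  mu_h <- (mu_a + mu_b) / 2                       # additive & null default
  mu_h[mode == "dominant_high"] <- hi[mode == "dominant_high"]
  mu_h[mode == "dominant_low"] <- lo[mode == "dominant_low"]
  mu_h[mode == "overdominant"] <- config$effect_size * hi[mode == "overdominant"]
  mu_h[mode == "underdominant"] <- lo[mode == "underdominant"] / config$effect_size

  reps <- config$n_reps_per_group
  sample_id <- c(sprintf("parentA_%d", seq_len(reps)),
                 sprintf("parentB_%d", seq_len(reps)),
                 sprintf("hybrid_%d", seq_len(reps)))
  groups <- stats::setNames(rep(GROUP_LEVELS, each = reps), sample_id)
  libf <- stats::runif(3 * reps, config$libsize_range[1], config$libsize_range[2])

  mu_mat <- cbind(matrix(mu_a, n, reps), matrix(mu_b, n, reps), matrix(mu_h, n, reps))
  mu_mat <- sweep(mu_mat, 2, libf, "*")
  if (config$dispersion == 0) {
    vals <- matrix(stats::rpois(n * 3 * reps, lambda = mu_mat), n, 3 * reps)
  } else {
    vals <- matrix(stats::rnbinom(n * 3 * reps, mu = mu_mat,
                                  size = 1 / config$dispersion), n, 3 * reps)
  }
  dimnames(vals) <- list(gene_id, sample_id)

  truth <- data.frame(gene_id = gene_id,
                      mode = mode,
                      mu_parentA = mu_a,
                      mu_parentB = mu_b,
                      mu_hybrid = mu_h,
                      stringsAsFactors = FALSE)
  list(expr = expression_matrix(vals, groups, scale = "counts"), truth = truth)
}

#' Trait simulation specification
#'
#' @param driver_genes Named list, one element per trait: a named numeric
#'   vector of signed weights, names being driver gene ids.
#' @param noise_sd Standard deviation of the additive Gaussian noise on each
#'   trait (>= 0).
#' @return A `TraitSimSpec` list.
#' @export
trait_sim_spec <- function(driver_genes, noise_sd = 1) {
  if (!is.list(driver_genes) || is.null(names(driver_genes)) ||
      any(!nzchar(names(driver_genes)))) {
    stop_config("driver_genes must be a named list (one element per trait)")
  }
  for (tr in names(driver_genes)) {
    w <- driver_genes[[tr]]
    if (!is.numeric(w) || is.null(names(w)) || any(!nzchar(names(w)))) {
      stop_config("weights for trait '%s' must be a named numeric vector", tr)
    }
  }
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(trait_names = names(driver_genes),
                 driver_genes = driver_genes,
                 noise_sd = noise_sd),
            class = "TraitSimSpec")
}

#' Simulate trait values coupled to designated driver genes
#'
#' Each trait value for sample `s` is the weighted sum of the drivers'
#' normalized expression in `s` plus Gaussian noise. Normalized expression
#' is the per-gene z-score of log2(CPM + 1) across samples, which is affine
#' in the log2 abundance used by [correlate_genes_traits()]; a single driver
#' with zero noise therefore correlates perfectly (r = +/-1 by the weight's
#' sign) with its trait.
#'
#' @param expr An [expression_matrix()] (any scale).
#' @param spec A [trait_sim_spec()].
#' @param seed Integer seed for the noise draws.
#' @return Trait table data.frame: `sample_id`, `group`, one numeric column
#'   per trait.
#' @export
simulate_traits <- function(expr, spec, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(spec, "TraitSimSpec"))
  all_drivers <- unique(unlist(lapply(spec$driver_genes, names)))
  missing <- setdiff(all_drivers, rownames(expr$values))
  if (length(missing)) {
    stop_lookup("driver gene(s) not in expression matrix: %s",
                paste(missing, collapse = ", "))
  }
  z <- normalized_driver_expression(expr, all_drivers)
  set.seed(as.integer(seed))
  n_s <- ncol(expr$values)
  out <- data.frame(sample_id = names(expr$groups),
                    group = as.character(expr$groups),
                    stringsAsFactors = FALSE)
  for (tr in spec$trait_names) {
    w <- spec$driver_genes[[tr]]
    signal <- as.numeric(crossprod(z[names(w), , drop = FALSE], w))
    out[[tr]] <- signal + stats::rnorm(n_s, 0, spec$noise_sd)
  }
  out
}

# Per-gene z-scores of log2(CPM + 1) for the requested genes.
normalized_driver_expression <- function(expr, genes) {
  v <- switch(expr$scale,
    counts = {
      totals <- colSums(expr$values)
      if (any(totals == 0)) stop_format("zero library size; cannot normalize")
      log2(sweep(expr$values[genes, , drop = FALSE] * 1e6, 2, totals, "/") + 1)
    },
    abundance = log2(expr$values[genes, , drop = FALSE] + 1),
    log2_abundance = expr$values[genes, , drop = FALSE]
  )
  d <- v - rowMeans(v)
  s <- sqrt(rowSums(d^2) / (ncol(v) - 1))
  s[s == 0] <- Inf   # constant gene -> z = 0
  d / s
}
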