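PATTERN_LEVELS <- c("transgressive_up", "transgressive_down",
                    "dominant_like", "additive_like", "unclassified")

#' Pattern-call configuration
#'
#' Thresholds used for the two hybrid-vs-parent contrasts that feed the
#' pattern classifier. The default gates on significance only
#' (`lfc_cutoff = 0`): the expression-pattern categories are defined by the
#' hybrid being significantly up- or down-regulated versus both parents,
#' with no fold-change requirement (that cutoff belongs to the volcano-style
#' DEG analysis, where [deg_thresholds()] defaults apply).
#'
#' @param thresholds A [deg_thresholds()] for the classification contrasts.
#' @param min_mpv Positive abundance floor below which MPH/BPH are undefined
#'   and the gene is excluded from classification.
#' @param additive_band Genes significant versus neither parent are labelled
#'   `additive_like` when |MPH| (in percent) is within this band, else
#'   `unclassified`. An extension beyond the transgressive categories.
#' @return A `PatternCallConfig` list.
#' @export
pattern_call_config <- function(thresholds = deg_thresholds(lfc_cutoff = 0),
                                min_mpv = 1,
                                additive_band = 20) {
  stopifnot(inherits(thresholds, "DEGThresholds"))
  if (min_mpv <= 0) stop_config("min_mpv must be positive")
  if (additive_band < 0) stop_config("additive_band must be >= 0")
  structure(list(thresholds = thresholds, min_mpv = min_mpv,
                 additive_band = additive_band),
            class = "PatternCallConfig")
}

#' Per-gene mid-parent and best-parent heterosis statistics
#'
#' For each gene, computes group mean abundances, the mid-parent value
#' `MPV = (mean_parentA + mean_parentB)/2`, the identity of the high parent
#' (the parent with the larger mean; ties resolved to parentA), and the
#' percent heterosis statistics
#' `MPH = 100 * (mean_hybrid - MPV)/MPV` and
#' `BPH = 100 * (mean_hybrid - high)/high`. Means are arithmetic means on
#' the abundance scale. Genes with `MPV < min_mpv` get `NA` MPH/BPH and are
#' excluded from classification; their count is reported via `message()`.
#'
#' @param expr An [expression_matrix()] on the abundance scale, with all
#'   three groups present.
#' @param min_mpv Positive MPV floor (default 1).
#' @return data.frame with columns `gene_id`, `mean_parentA`, `mean_parentB`,
#'   `mean_hybrid`, `mpv`, `high_parent`, `mph_pct`, `bph_pct`, `pattern`
#'   (`NA`, set by [classify_patterns()]) and `candidate` (`NA`).
#' @export
compute_heterosis_stats <- function(expr, min_mpv = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "abundance") {
    stop_usage("compute_heterosis_stats expects an abundance-scale matrix")
  }
  if (nlevels(droplevels(expr$groups)) < 3) {
    stop_usage("all three groups (parentA, parentB, hybrid) are required")
  }
  gm <- group_means(expr)
  mpv <- (gm[, "parentA"] + gm[, "parentB"]) / 2
  high_is_b <- gm[, "parentB"] > gm[, "parentA"]
  n_ties <- sum(gm[, "parentA"] == gm[, "parentB"])
  if (n_ties > 0) {
    message(sprintf("high-parent ties for %d gene(s); resolved to parentA", n_ties))
  }
  high_parent <- ifelse(high_is_b, "parentB", "parentA")
  high_mean <- pmax(gm[, "parentA"], gm[, "parentB"])
  defined <- mpv >= min_mpv
  if (any(!defined)) {
    message(sprintf("MPH/BPH undefined for %d gene(s) with MPV < %g",
                    sum(!defined), min_mpv))
  }
  mph <- ifelse(defined, 100 * (gm[, "hybrid"] - mpv) / mpv, NA_real_)
  bph <- ifelse(defined, 100 * (gm[, "hybrid"] - high_mean) / high_mean, NA_real_)
  data.frame(gene_id = rownames(expr$values),
             mean_parentA = as.numeric(gm[, "parentA"]),
             mean_parentB = as.numeric(gm[, "parentB"]),
             mean_hybrid = as.numeric(gm[, "hybrid"]),
             mpv = as.numeric(mpv),
             high_parent = high_parent,
             mph_pct = as.numeric(mph),
             bph_pct = as.numeric(bph),
             pattern = NA_character_,
             candidate = NA,
             stringsAsFactors = FALSE)
}

#' Classify genes into heterosis expression patterns
#'
#' Uses the significance calls of the two hybrid-vs-parent contrasts (the
#' hybrid must be the test group in both):
#' * `transgressive_up` (overdominance): up in the hybrid versus both parents;
#' * `transgressive_down` (underdominance): down versus both parents;
#' * `dominant_like`: significant versus exactly one parent;
#' * `additive_like`: significant versus neither parent and |MPH| within the
#'   additive band;
#' * `unclassified`: everything else (including the rare up-vs-one /
#'   down-vs-other case).
#' The transgressive and dominant classes are purely significance-based, so
#' genes with undefined MPH (MPV below the floor) can still receive them;
#' such genes can never be `additive_like` (the band needs MPH) nor
#' candidates (candidacy needs BPH > 0).
#' Candidates are transgressive-up genes with strictly positive BPH.
#'
#' @param records Output of [compute_heterosis_stats()].
#' @param deg_vs_parentA,deg_vs_parentB [run_contrast()] results with
#'   `reference` the respective parent and `test = "hybrid"`, covering the
#'   same genes as `records`.
#' @param config A [pattern_call_config()] (supplies the additive band; the
#'   significance decisions are taken from the DEG records' `call` column).
#' @return `records` with `pattern` and `candidate` filled in.
#' @export
classify_patterns <- function(records, deg_vs_parentA, deg_vs_parentB,
                              config = pattern_call_config()) {
  stopifnot(inherits(config, "PatternCallConfig"))
  for (deg in list(deg_vs_parentA, deg_vs_parentB)) {
    if (!all(c("gene_id", "reference", "test", "call") %in% names(deg))) {
      stop_usage("DEG records must come from run_contrast()")
    }
    if (any(deg$test != "hybrid")) {
      stop_usage("classification contrasts must have the hybrid as test group")
    }
  }
  if (any(deg_vs_parentA$reference != "parentA") ||
      any(deg_vs_parentB$reference != "parentB")) {
    stop_usage("contrast orientation mismatch: expected parentA and parentB references")
  }
  if (!setequal(records$gene_id, deg_vs_parentA$gene_id) ||
      !setequal(records$gene_id, deg_vs_parentB$gene_id)) {
    stop_usage("DEG records must cover the same gene universe as the heterosis records")
  }
  call_a <- deg_vs_parentA$call[match(records$gene_id, deg_vs_parentA$gene_id)]
  call_b <- deg_vs_parentB$call[match(records$gene_id, deg_vs_parentB$gene_id)]

  up_a <- call_a == "up_in_test";   up_b <- call_b == "up_in_test"
  dn_a <- call_a == "down_in_test"; dn_b <- call_b == "down_in_test"
  sig_a <- up_a | dn_a; sig_b <- up_b | dn_b

  pattern <- rep("unclassified", nrow(records))
  pattern[xor(sig_a, sig_b)] <- "dominant_like"
  neither <- !sig_a & !sig_b
  in_band <- !is.na(records$mph_pct) & abs(records$mph_pct) <= config$additive_band
  pattern[neither & in_band] <- "additive_like"
  pattern[up_a & up_b] <- "transgressive_up"
  pattern[dn_a & dn_b] <- "transgressive_down"

  records$pattern <- pattern
  records$candidate <- !is.na(pattern) & pattern == "transgressive_up" &
    !is.na(records$bph_pct) & records$bph_pct > 0
  records
}

#' Hybrid-vigor candidate genes
#'
#' Transgressive-up (overdominant) genes with strictly positive best-parent
#' heterosis, ordered by decreasing BPH.
#'
#' @param records Classified records from [classify_patterns()].
#' @return Character vector of gene ids.
#' @export
select_candidates <- function(records) {
  if (!nrow(records)) return(character())
  if (all(is.na(records$pattern))) stop_usage("patterns not set; run classify_patterns()")
  keep <- !is.na(records$pattern) & records$pattern == "transgressive_up" &
    !is.na(records$bph_pct) & records$bph_pct > 0
  sel <- records[keep, , drop = FALSE]
  sel$gene_id[order(sel$bph_pct, decreasing = TRUE)]
}

#' Intersection of the hybrid's upregulated gene sets
#'
#' Genes called `up_in_test` (hybrid) in both hybrid-vs-parent contrasts.
#' By construction this equals the `transgressive_up` set of
#' [classify_patterns()] when both consume the same DEG records.
#'
#' @param deg_vs_parentA,deg_vs_parentB [run_contrast()] results with the
#'   hybrid as test group.
#' @return Sorted character vector of gene ids.
#' @export
intersect_upregulated <- function(deg_vs_parentA, deg_vs_parentB) {
  up_a <- deg_vs_parentA$gene_id[deg_vs_parentA$call == "up_in_test"]
  up_b <- deg_vs_parentB$gene_id[deg_vs_parentB$call == "up_in_test"]
  sort(intersect(up_a, up_b))
}
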