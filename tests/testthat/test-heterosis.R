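test_that("MPV, MPH and BPH follow the closed-form definitions", {
  em <- toy_expr(matrix(c(10, 10, 10,   20, 20, 20,   18, 15, 30), 3),
                 n_reps = 3)
  het <- suppressMessages(compute_heterosis_stats(em))
  # parents 10/20, hybrid 18: MPV 15, MPH +20%, BPH -10%
  expect_equal(het$mpv[1], 15)
  expect_equal(het$mph_pct[1], 20)
  expect_equal(het$bph_pct[1], -10)
  expect_identical(het$high_parent[1], "parentB")
  # hybrid equal to MPV: zero mid-parent heterosis
  expect_equal(het$mph_pct[2], 0)
  # hybrid 30 above both parents: MPH +100, BPH +50
  expect_equal(het$mph_pct[3], 100)
  expect_equal(het$bph_pct[3], 50)
})

test_that("MPH >= BPH and the BPH sign rule hold on randomized triples", {
  set.seed(33)
  n <- 5000
  a <- rlnorm(n, 3, 1.5); b <- rlnorm(n, 3, 1.5); h <- rlnorm(n, 3, 1.5)
  em <- toy_expr(cbind(a, b, h), n_reps = 2)
  het <- suppressMessages(compute_heterosis_stats(em, min_mpv = 1e-12))
  expect_true(all(het$mph_pct >= het$bph_pct))
  expect_identical(het$bph_pct > 0, h > pmax(a, b))
  expect_identical(het$mean_hybrid < pmin(a, b), het$bph_pct < 0 &
                     het$mean_hybrid < pmin(het$mean_parentA, het$mean_parentB))
})

test_that("low-MPV genes get undefined heterosis statistics", {
  em <- toy_expr(matrix(c(0.2, 50, 0.4, 50, 5, 75), 2), n_reps = 2)
  expect_message(het <- compute_heterosis_stats(em, min_mpv = 1),
                 "1 gene")
  expect_true(is.na(het$mph_pct[1]) && is.na(het$bph_pct[1]))
  expect_false(is.na(het$mph_pct[2]))
})

test_that("pattern classification applies the category rules", {
  genes <- sprintf("g%02d", 1:6)
  em <- toy_expr(matrix(c(10, 10, 10, 10, 10, 10,
                          20, 20, 20, 20, 20, 20,
                          40, 5, 18, 15, 40, 5), 6), n_reps = 2)
  rownames(em$values) <- NULL; rownames(em$values) <- rep(genes, 1)
  het <- suppressMessages(compute_heterosis_stats(em))
  het$gene_id <- genes
  deg_a <- toy_deg(genes, c("up_in_test", "down_in_test", "not_significant",
                            "down_in_test", "up_in_test", "down_in_test"),
                   reference = "parentA")
  deg_b <- toy_deg(genes, c("up_in_test", "down_in_test", "not_significant",
                            "not_significant", "down_in_test", "up_in_test"),
                   reference = "parentB")
  out <- classify_patterns(het, deg_a, deg_b)
  expect_identical(out$pattern,
                   c("transgressive_up", "transgressive_down", "additive_like",
                     "dominant_like", "unclassified", "unclassified"))
  # candidate: transgressive_up with BPH > 0 (gene 1: hybrid 40 > 20)
  expect_identical(out$candidate, c(TRUE, rep(FALSE, 5)))
})

test_that("additive band separates additive_like from unclassified", {
  genes <- c("in_band", "out_band")
  em <- toy_expr(matrix(c(10, 10, 20, 20, 16, 25), 2), n_reps = 2)
  rownames(em$values) <- genes
  het <- suppressMessages(compute_heterosis_stats(em))
  het$gene_id <- genes
  ns <- toy_deg(genes, rep("not_significant", 2), reference = "parentA")
  nsb <- toy_deg(genes, rep("not_significant", 2), reference = "parentB")
  out <- classify_patterns(het, ns, nsb,
                           pattern_call_config(additive_band = 20))
  # MPH: gene1 (16-15)/15 = +6.7% in band; gene2 (25-15)/15 = +66.7% out
  expect_identical(out$pattern, c("additive_like", "unclassified"))
})

test_that("contrast orientation is validated", {
  em <- toy_expr(matrix(c(10, 20, 30), 1), n_reps = 2)
  het <- suppressMessages(compute_heterosis_stats(em))
  het$gene_id <- rownames(em$values)
  good_a <- toy_deg(het$gene_id, "up_in_test", reference = "parentA")
  flipped <- toy_deg(het$gene_id, "up_in_test", reference = "hybrid",
                     test = "parentB")
  expect_error(classify_patterns(het, good_a, flipped),
               class = "hvigor_usage_error")
  wrong_ref <- toy_deg(het$gene_id, "up_in_test", reference = "parentB")
  expect_error(classify_patterns(het, wrong_ref, wrong_ref),
               "orientation", class = "hvigor_usage_error")
})

test_that("candidates are transgressive-up genes with BPH > 0, sorted", {
  records <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    bph_pct = c(35, 0, 80, 12),
    pattern = c("transgressive_up", "transgressive_up", "transgressive_up",
                "transgressive_down"),
    stringsAsFactors = FALSE)
  expect_identical(select_candidates(records), c("c", "a"))  # b: BPH 0 excluded
  expect_identical(select_candidates(records[0, ]), character())
})

test_that("intersect_upregulated is plain set intersection", {
  deg_a <- toy_deg(c("A", "B", "C", "D"),
                   c("up_in_test", "up_in_test", "up_in_test", "not_significant"),
                   reference = "parentA")
  deg_b <- toy_deg(c("A", "B", "C", "D"),
                   c("not_significant", "up_in_test", "up_in_test", "up_in_test"),
                   reference = "parentB")
  expect_identical(intersect_upregulated(deg_a, deg_b), c("B", "C"))
  deg_b2 <- deg_b; deg_b2$call <- "down_in_test"
  expect_identical(intersect_upregulated(deg_a, deg_b2), character())
})

test_that("classified patterns partition the gene universe", {
  sim <- simulate_expression(sim_config(n_genes = 1500, seed = 17))
  ab <- normalize_abundance(sim$expr)
  thr <- deg_thresholds(lfc_cutoff = 0)
  ca <- run_contrast(ab, "parentA", "hybrid", thr)
  cb <- run_contrast(ab, "parentB", "hybrid", thr)
  het <- suppressMessages(compute_heterosis_stats(ab))
  out <- classify_patterns(het, ca, cb)
  expect_false(any(is.na(out$pattern)))
  expect_identical(sum(table(out$pattern)), 1500L)
  # internal consistency with the intersected up-sets
  expect_identical(sort(out$gene_id[out$pattern == "transgressive_up"]),
                   intersect_upregulated(ca, cb))
})
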