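test_that("Tukey pairwise p-values match the stock implementation", {
  set.seed(61)
  groups <- rep(c("parentA", "parentB", "hybrid"), each = 6)
  values <- c(rnorm(6, 10, 1.5), rnorm(6, 12, 1.5), rnorm(6, 11, 1.5))
  got <- tukey_hsd(values, groups)
  ref <- TukeyHSD(aov(values ~ g, data.frame(values, g = factor(groups))))$g
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  got_p <- setNames(got$pairwise$p_adj,
                    mapply(key, got$pairwise$group1, got$pairwise$group2))
  ref_names <- strsplit(rownames(ref), "-", fixed = TRUE)
  for (i in seq_along(ref_names)) {
    k <- key(ref_names[[i]][1], ref_names[[i]][2])
    expect_equal(unname(got_p[k]), unname(ref[i, "p adj"]), tolerance = 1e-6)
  }
})

test_that("Tukey handles unbalanced designs via the Kramer adjustment", {
  set.seed(62)
  groups <- c(rep("parentA", 4), rep("parentB", 7), rep("hybrid", 5))
  values <- rnorm(16, rep(c(5, 6.5, 8), c(4, 7, 5)), 1)
  got <- tukey_hsd(values, groups)
  ref <- TukeyHSD(aov(values ~ g, data.frame(values, g = factor(groups))))$g
  expect_equal(sort(got$pairwise$p_adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-6)
})

test_that("well-separated groups receive distinct letters, identical data one", {
  groups <- rep(c("parentA", "parentB", "hybrid"), each = 4)
  sep <- c(rnorm(4, 0, 0.01), rnorm(4, 100, 0.01), rnorm(4, 200, 0.01))
  set.seed(63)
  res <- tukey_hsd(sep + rnorm(12, 0, 1e-3), groups)
  expect_identical(length(unique(res$letters)), 3L)
  flat <- tukey_hsd(rep(5, 12), groups)
  expect_true(all(flat$pairwise$p_adj == 1))
  expect_identical(unique(unname(flat$letters)), "a")
})

test_that("compact letter display is sound and complete on random tables", {
  set.seed(64)
  for (rep in 1:200) {
    k <- sample(3:6, 1)
    g <- letters[1:k]
    pairs <- t(combn(g, 2))
    sig_rows <- runif(nrow(pairs)) < 0.4
    sig <- data.frame(group1 = pairs[sig_rows, 1], group2 = pairs[sig_rows, 2],
                      stringsAsFactors = FALSE)
    cld <- hvigor:::cld_letters(g, sig)
    shares <- function(a, b) {
      length(intersect(strsplit(cld[[a]], "")[[1]],
                       strsplit(cld[[b]], "")[[1]])) > 0
    }
    for (i in seq_len(nrow(pairs))) {
      is_sig <- any(sig$group1 == pairs[i, 1] & sig$group2 == pairs[i, 2])
      # significant pairs share no letter; non-significant pairs share one
      expect_identical(shares(pairs[i, 1], pairs[i, 2]), !is_sig)
    }
  }
})

test_that("gene-trait correlation matches the closed-form Pearson oracle", {
  set.seed(65)
  em <- toy_expr(matrix(rlnorm(15, 4, 1), 5), n_reps = 4, noise_sd = 0.5)
  traits <- data.frame(sample_id = colnames(em$values),
                       group = unname(em$groups),
                       shear = rnorm(12, 40, 5),
                       ph = rnorm(12, 5.6, 0.2),
                       stringsAsFactors = FALSE)
  res <- correlate_genes_traits(em, traits)
  for (i in seq_len(nrow(res))) {
    x <- log2(em$values[res$gene_id[i], traits$sample_id] + 1)
    y <- traits[[res$trait[i]]]
    o <- pearson_oracle(x, y)
    expect_equal(res$r[i], o$r, tolerance = 1e-10)
    expect_equal(res$p_value[i], o$p, tolerance = 1e-10)
    ct <- cor.test(x, y)
    expect_equal(res$p_value[i], ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation is invariant to affine transforms of the trait", {
  set.seed(66)
  em <- toy_expr(matrix(rlnorm(9, 4, 1), 3), n_reps = 4, noise_sd = 0.5)
  traits <- data.frame(sample_id = colnames(em$values),
                       group = unname(em$groups),
                       t1 = rnorm(12), stringsAsFactors = FALSE)
  shifted <- traits
  shifted$t1 <- 3 * traits$t1 - 7
  a <- correlate_genes_traits(em, traits)
  b <- correlate_genes_traits(em, shifted)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  negated <- traits
  negated$t1 <- -traits$t1
  c_ <- correlate_genes_traits(em, negated)
  expect_equal(a$r, -c_$r, tolerance = 1e-12)
})

test_that("a noiseless simulated driver correlates perfectly with its trait", {
  sim <- simulate_expression(sim_config(n_genes = 80, seed = 21))
  cpm <- suppressWarnings(normalize_fpkm(sim$expr))
  spec <- trait_sim_spec(list(up = setNames(1, "gene00005"),
                              down = setNames(-1, "gene00005")), noise_sd = 0)
  traits <- simulate_traits(sim$expr, spec, seed = 2)
  res <- correlate_genes_traits(cpm, traits, genes = "gene00005")
  expect_equal(res$r[res$trait == "up"], 1, tolerance = 1e-9)
  expect_equal(res$r[res$trait == "down"], -1, tolerance = 1e-9)
  expect_identical(res$stars[res$trait == "up"], "***")
})

test_that("constant vectors yield NA correlations, not errors", {
  em <- toy_expr(matrix(rep(5, 3), 1), n_reps = 4)
  traits <- data.frame(sample_id = colnames(em$values),
                       group = unname(em$groups),
                       t1 = rnorm(12), stringsAsFactors = FALSE)
  res <- correlate_genes_traits(em, traits)
  expect_true(is.na(res$r) && is.na(res$p_value))
  expect_identical(res$stars, "")
})

test_that("significance stars follow the conventional cutoffs", {
  expect_identical(hvigor:::star_codes(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("", "*", "**", "***", ""))
  expect_identical(hvigor:::star_codes(c(0.05, 0.01, 0.001)), c("", "*", "**"))
})

test_that("trait summaries report group means, dispersion and letters", {
  set.seed(67)
  traits <- data.frame(
    sample_id = sprintf("s%02d", 1:18),
    group = rep(c("parentA", "parentB", "hybrid"), each = 6),
    shear = c(rnorm(6, 30, 1), rnorm(6, 60, 1), rnorm(6, 45, 1)),
    stringsAsFactors = FALSE)
  sm <- summarize_traits(traits)
  sh <- sm[sm$trait == "shear", ]
  expect_identical(nrow(sh), 3L)
  expect_equal(sh$mean[sh$group == "parentA"],
               mean(traits$shear[traits$group == "parentA"]), tolerance = 1e-12)
  expect_identical(length(unique(sh$letters)), 3L)   # all groups differ
  expect_equal(sh$sd[sh$group == "hybrid"],
               sd(traits$shear[traits$group == "hybrid"]), tolerance = 1e-12)
})
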