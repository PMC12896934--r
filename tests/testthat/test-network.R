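test_that("the centre of a star graph is the top hub", {
  edges <- data.frame(from = rep("HUB", 5),
                      to = c("L1", "L2", "L3", "L4", "L5"),
                      stringsAsFactors = FALSE)
  top <- hub_genes(edges, k = 1)
  expect_identical(top$gene_id, "HUB")
  expect_identical(top$degree, 5L)
  expect_identical(top$rank, 1L)
})

test_that("degree ties are broken lexicographically by gene id", {
  # triangle: all three nodes have degree 2
  edges <- data.frame(from = c("ZZ", "MM", "AA"), to = c("MM", "AA", "ZZ"),
                      stringsAsFactors = FALSE)
  top <- hub_genes(edges, k = 3)
  expect_identical(top$gene_id, c("AA", "MM", "ZZ"))
  expect_identical(top$degree, rep(2L, 3))
})

test_that("reported degrees match brute-force edge counting", {
  set.seed(71)
  nodes <- sprintf("n%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  edges <- as.data.frame(pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE],
                         stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  top <- hub_genes(edges, k = 12)
  for (i in seq_len(nrow(top))) {
    g <- top$gene_id[i]
    expect_identical(top$degree[i],
                     sum(edges$from == g) + sum(edges$to == g))
  }
  expect_true(all(diff(top$degree) <= 0))
})

test_that("hub ranking is invariant to edge order and orientation", {
  set.seed(72)
  edges <- data.frame(from = c("A", "B", "C", "A", "D"),
                      to = c("B", "C", "D", "C", "E"),
                      stringsAsFactors = FALSE)
  shuffled <- edges[sample(nrow(edges)), ]
  flipped <- data.frame(from = shuffled$to, to = shuffled$from,
                        stringsAsFactors = FALSE)
  expect_identical(hub_genes(edges, k = 5), hub_genes(flipped, k = 5))
})

test_that("query restriction induces the subgraph before ranking", {
  edges <- data.frame(from = c("A", "A", "A", "B", "X"),
                      to = c("B", "C", "X", "C", "Y"),
                      stringsAsFactors = FALSE)
  # within {A,B,C}: A has degree 2, the A-X edge must not count
  top <- hub_genes(edges, query = c("A", "B", "C"), k = 3)
  expect_identical(top$degree[top$gene_id == "A"], 2L)
  expect_setequal(top$gene_id, c("A", "B", "C"))
  # query nodes with no surviving edges are dropped, leaving nothing here
  expect_warning(lone <- hub_genes(edges, query = c("A", "Y"), k = 5), "empty")
  expect_identical(lone$gene_id, character(0))
  expect_warning(empty <- hub_genes(edges, query = "nope", k = 2), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("enrichment p-values match the exact big-integer oracle", {
  set.seed(73)
  universe <- sprintf("u%03d", 1:200)
  sets <- list(
    s_small = universe[1:8],
    s_mid = universe[5:60],
    s_big = universe[c(1:40, 150:200)])
  query <- universe[c(1:6, 50:55, 120:130)]
  res <- enrich(query, sets, universe)
  for (i in seq_len(nrow(res))) {
    o <- hyper_tail_oracle(k = res$overlap[i], K = res$set_size[i],
                           N = res$universe_size[i], n = res$query_size[i])
    expect_equal(res$p_value[i], o, tolerance = 1e-9)
  }
  expect_equal(res$p_adjusted, bh_oracle(res$p_value), tolerance = 1e-12)
})

test_that("a query equal to a whole set is maximally enriched", {
  universe <- sprintf("g%04d", 1:1000)
  sets <- list(target = universe[1:20])
  res <- enrich(universe[1:20], sets, universe)
  expect_identical(res$overlap, 20L)
  # P(X >= 20) when drawing the 20 set members exactly: 1/choose(1000,20)
  expect_equal(res$p_value, 1 / choose(1000, 20), tolerance = 1e-9)
  expect_equal(res$p_value,
               hyper_tail_oracle(20, 20, 1000, 20), tolerance = 1e-9)
})

test_that("zero overlap gives p = 1 and an empty gene string", {
  universe <- sprintf("g%03d", 1:100)
  res <- enrich(universe[51:60], list(s = universe[1:10]), universe)
  expect_identical(res$overlap, 0L)
  expect_equal(res$p_value, 1)
  expect_identical(res$genes, "")
})

test_that("query genes outside the universe are dropped with a message", {
  universe <- c("A", "B", "C", "D")
  expect_message(res <- enrich(c("A", "B", "ALIEN"), list(s = c("A", "B")),
                               universe),
                 "dropped 1")
  expect_identical(res$query_size, 2L)
  expect_identical(res$overlap, 2L)
})

test_that("shrinking the universe strengthens a fixed overlap", {
  sets <- list(s = sprintf("g%03d", 1:10))
  query <- sprintf("g%03d", 1:5)
  p_wide <- enrich(query, sets, sprintf("g%03d", 1:500))$p_value
  p_narrow <- enrich(query, sets, sprintf("g%03d", 1:50))$p_value
  expect_lt(p_wide, p_narrow)
})

test_that("results are sorted by p-value with BH across all sets", {
  universe <- sprintf("g%03d", 1:300)
  sets <- list(zzz = universe[1:10], aaa = universe[1:10],
               weak = universe[200:280])
  res <- suppressMessages(enrich(universe[1:10], sets, universe))
  expect_true(!is.unsorted(res$p_value))
  # equal p-values tie-break by set name
  expect_identical(res$set_name[1:2], c("aaa", "zzz"))
  expect_equal(res$p_adjusted, bh_oracle(res$p_value), tolerance = 1e-12)
})
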