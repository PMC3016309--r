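test_that("annotation permutation preserves sizes and co-annotation structure", {
  gs <- gene_sets(list(
    A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
    C = c("g1", "g4", "g5", "g6")
  ))
  sizes <- function(g) lengths(cbpln:::set_list(g))
  co <- function(g, s1, s2) {
    sl <- cbpln:::set_list(g)
    length(intersect(sl[[s1]], sl[[s2]]))
  }
  for (seed in 1:10) {
    perm <- permute_annotations(gs, seed = seed)
    expect_equal(sizes(perm), sizes(gs))
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      expect_equal(co(perm, pair[1], pair[2]), co(gs, pair[1], pair[2]))
    }
    # triple-wise co-annotation
    sl <- cbpln:::set_list(perm)
    expect_length(Reduce(intersect, sl), length(Reduce(intersect, cbpln:::set_list(gs))))
    expect_equal(sort(unique(perm$gene)), gene_universe(gs))
  }

  # single-gene universe: only the identity is possible
  one <- gene_sets(list(A = "g1"))
  expect_equal(cbpln:::set_list(permute_annotations(one, 3)), cbpln:::set_list(one))
})

test_that("edge swaps preserve degrees, nodes, weights and simplicity", {
  for (seed in 1:5) {
    w <- random_world(seed)
    sw <- swap_edges(w$network, swap_multiplier = 5, seed = seed + 50)
    expect_equal(network_nodes(sw), network_nodes(w$network))
    deg <- function(n) sort(table(c(n$from, n$to)))
    expect_equal(
      sort(as.integer(deg(sw))),
      sort(as.integer(deg(w$network)))
    )
    # per-node degree, not just the sorted sequence
    d1 <- table(c(sw$from, sw$to))
    d2 <- table(c(w$network$from, w$network$to))
    expect_equal(as.integer(d1[names(d2)]), as.integer(d2))
    expect_equal(sort(sw$weight), sort(w$network$weight))
    expect_false(any(sw$from == sw$to))
    expect_false(any(duplicated(paste(sw$from, sw$to))))
  }
})

test_that("swap-resistant graphs come back unchanged", {
  # path a-b-c: both candidate rewirings are self-loops or existing edges
  path <- fin_network(data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 2)))
  for (seed in 1:5) {
    expect_equal(swap_edges(path, 50, seed = seed), path)
  }
  # complete graph K4: every candidate edge already exists
  k4 <- fin_network(data.frame(
    t(utils::combn(letters[1:4], 2)),
    weight = 1
  ) |> stats::setNames(c("from", "to", "weight")))
  for (seed in 1:3) {
    expect_equal(swap_edges(k4, 20, seed = seed), k4)
  }
  # Q = 0 is the identity
  w <- random_world(2)
  expect_equal(swap_edges(w$network, 0, seed = 1), w$network)
})

test_that("two disjoint edges admit exactly the two rewirings, each about half the time", {
  net <- fin_network(data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1))
  seen <- character(0)
  for (seed in 1:200) {
    sw <- swap_edges(net, 1, seed = seed)
    seen <- c(seen, paste(paste(sw$from, sw$to), collapse = ";"))
  }
  counts <- table(seen)
  # both rewirings occur; originals can only survive via an odd swap trail
  expect_true(all(c("a d;b c", "a c;b d") %in% names(counts)))
  expect_gt(min(counts[c("a d;b c", "a c;b d")]), 30)
})

test_that("empirical p-values follow the strict 'larger than' rule", {
  expect_equal(empirical_pvalue(8.5, 1:10), 0.2)
  expect_equal(empirical_pvalue(10, 1:10), 0.0)
  expect_equal(empirical_pvalue(5, c(5, 5, 5, 5)), 0.0) # ties do not count
  expect_equal(empirical_pvalue(0, 1:10), 1.0)
  expect_equal(empirical_pvalue(5, c(5, 5, 5, 5), pseudocount = TRUE), 1 / 5)
  expect_equal(empirical_pvalue(10, 1:10, pseudocount = TRUE), 1 / 11)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("BH adjustment matches hand-derived values and the step-up oracle", {
  expect_equal(bh_adjust_monotone(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust_monotone(c(0.005, 0.02, 0.9)), c(0.015, 0.03, 0.9))
  expect_equal(bh_adjust_monotone(0.37), 0.37)
  expect_error(bh_adjust_monotone(c(0.1, 1.2)), "\\[0, 1\\]")
  for (seed in 1:20) {
    p <- withr::with_seed(seed, stats::runif(sample(1:15, 1)))
    expect_equal(bh_adjust_monotone(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("gene-set null distributions are seeded, sized and sane", {
  w <- random_world(5)
  nd <- geneset_null_distribution(
    w$network, w$perturbation, w$genesets, "S01", "S02",
    permutations = 40, seed = 9
  )
  expect_s3_class(nd, "null_distribution")
  expect_length(nd$values, 40)
  nd2 <- geneset_null_distribution(
    w$network, w$perturbation, w$genesets, "S01", "S02",
    permutations = 40, seed = 9
  )
  expect_identical(nd$values, nd2$values) # bit-identical under the same seed
  nd3 <- geneset_null_distribution(
    w$network, w$perturbation, w$genesets, "S01", "S02",
    permutations = 1, seed = 9
  )
  expect_length(nd3$values, 1)

  # randomizing the source instead of the target is supported and seeded
  nds <- geneset_null_distribution(
    w$network, w$perturbation, w$genesets, "S01", "S02",
    permutations = 15, seed = 4, randomize = "source"
  )
  expect_length(nds$values, 15)
  expect_identical(nds$values, geneset_null_distribution(
    w$network, w$perturbation, w$genesets, "S01", "S02",
    permutations = 15, seed = 4, randomize = "source"
  )$values)
})

test_that("gene-set null converges to the exact permutation law under unit inputs", {
  w <- random_world(12, unit = TRUE)
  a <- "S01"
  b <- "S03"
  restricted <- restrict_to_annotated(w$network, w$genesets)
  ns <- neighbor_sets(restricted, w$genesets, a, b)
  obs <- length(ns$n_ab)
  nd <- geneset_null_distribution(
    w$network, w$perturbation, w$genesets, a, b,
    permutations = 4000, seed = 11, normalize = FALSE
  )
  p_emp <- empirical_pvalue(obs, nd)
  n_u <- length(gene_universe(w$genesets))
  n_na <- length(ns$n_a)
  p_exact <- oracle_perm_tail_strict(n_u, n_na, 12, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_emp - p_exact), 3 * se + 1e-12)
})

test_that("network null on swap-resistant graphs degenerates at the observed score", {
  net <- fin_network(data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(0.8, 0.6)))
  gs <- gene_sets(list(A = "a", B = c("b", "c")))
  pt <- perturbation(data.frame(gene = c("a", "b", "c"), pvalue = c(0.01, 0.05, 0.2)))
  obs <- contextual_linkage_score(net, pt, gs, "A", "B")$score
  nd <- network_null_distribution(net, pt, gs, "A", "B",
    permutations = 25, swap_multiplier = 10, seed = 6, normalize = FALSE
  )
  expect_true(all(nd$values == obs))
  expect_equal(empirical_pvalue(obs, nd), 0) # strict rule on an all-tie null
  # reproducible under the same seed
  nd2 <- network_null_distribution(net, pt, gs, "A", "B",
    permutations = 25, swap_multiplier = 10, seed = 6, normalize = FALSE
  )
  expect_identical(nd$values, nd2$values)
})
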