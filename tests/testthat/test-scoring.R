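test_that("neighbor contribution is the max confidence-weighted neighbor score", {
  net <- toy_network()
  gs <- toy_genesets()
  pt <- toy_perturbation()
  expect_equal(neighbor_contribution(net, pt, gs, "A", "b1"), 1.6) # max(0.8*2, 0.5*1)
  expect_equal(neighbor_contribution(net, pt, gs, "A", "b2"), 1.0)
  expect_equal(neighbor_contribution(net, pt, gs, "B", "a2"), 2.0) # max(0.5*3, 1.0*2)
  # no source-annotated neighbor -> 0
  gs2 <- gene_sets(list(A = "c1", B = c("b1", "b2")))
  expect_equal(neighbor_contribution(net, pt, gs2, "A", "b2"), 0)
})

test_that("contextual linkage score reproduces the worked example and its parts", {
  res <- contextual_linkage_score(toy_network(), toy_perturbation(), toy_genesets(), "A", "B")
  expect_equal(res$score, 6.8)
  expect_equal(res$contributions$gene, c("b1", "b2"))
  expect_equal(res$contributions$product, c(4.8, 2.0))
  expect_equal(sum(res$contributions$product), res$score)

  # empty neighborhood scores 0
  gs <- gene_sets(list(A = c("a1", "a2", "c1"), B = c("b1", "b2", "c1"), D = "d9"))
  expect_equal(contextual_linkage_score(toy_network(), toy_perturbation(), gs, "D", "B")$score, 0)
})

test_that("background score uses the mean measured score and normalization subtracts it", {
  s_bg <- background_score(toy_network(), toy_perturbation(), toy_genesets(), "A", "B")
  expect_equal(s_bg, 10.368) # mean s = 2.4; 2.4*(0.8*2.4) + 2.4*(1.0*2.4)
  expect_equal(normalized_score(6.8, s_bg), -3.568)
  expect_equal(normalized_score(5, 0), 5)
  expect_equal(normalized_score(3.2, 3.2), 0)

  # constant scores are a fixed point: S == S_bg
  pt_const <- perturbation(data.frame(
    gene = c("a1", "a2", "b1", "b2", "c1"), pvalue = rep(0.01, 5)
  ))
  s <- contextual_linkage_score(toy_network(), pt_const, toy_genesets(), "A", "B")$score
  expect_equal(background_score(toy_network(), pt_const, toy_genesets(), "A", "B"), s)

  # no measured genes -> validation error
  pt_none <- perturbation(data.frame(gene = "zz", pvalue = 0.5))
  gs <- toy_genesets()
  expect_error(background_score(toy_network(), pt_none, gs, "A", "B"), "measured")
})

test_that("with unit scores and weights the score reduces to the interactor count", {
  for (seed in 1:6) {
    w <- random_world(seed, unit = TRUE)
    procs <- process_ids(w$genesets)
    for (a in procs) {
      for (b in setdiff(procs, a)) {
        ns <- neighbor_sets(w$network, w$genesets, a, b)
        sc <- contextual_linkage_score(w$network, w$perturbation, w$genesets, a, b)
        expect_identical(sc$score, as.numeric(length(ns$n_ab)))
      }
    }
  }
})

test_that("the indexed scorer agrees with a naive double-loop oracle", {
  for (seed in c(3, 9)) {
    w <- random_world(seed, n_genes = 30, n_sets = 3, set_size = 8, edge_prob = 0.15)
    procs <- process_ids(w$genesets)
    for (a in procs) {
      for (b in setdiff(procs, a)) {
        got <- contextual_linkage_score(w$network, w$perturbation, w$genesets, a, b)$score
        expect_equal(got, oracle_score(w$network, w$perturbation, w$genesets, a, b),
          tolerance = 1e-9
        )
      }
    }
  }
})

test_that("score scales quadratically in gene scores and linearly in weights", {
  w <- random_world(4)
  a <- "S01"
  b <- "S02"
  s0 <- contextual_linkage_score(w$network, w$perturbation, w$genesets, a, b)$score
  bg0 <- background_score(w$network, w$perturbation, w$genesets, a, b)
  expect_gt(s0, 0)

  pt2 <- w$perturbation
  pt2$score <- pt2$score * 2
  expect_equal(contextual_linkage_score(w$network, pt2, w$genesets, a, b)$score, 4 * s0)
  expect_equal(background_score(w$network, pt2, w$genesets, a, b), 4 * bg0)

  net2 <- w$network
  net2$weight <- net2$weight * 2
  expect_equal(contextual_linkage_score(net2, w$perturbation, w$genesets, a, b)$score, 2 * s0)
  expect_equal(background_score(net2, w$perturbation, w$genesets, a, b), 2 * bg0)
})

test_that("raising a source gene's score or any weight never lowers the score", {
  w <- random_world(8)
  a <- "S01"
  b <- "S03"
  base <- contextual_linkage_score(w$network, w$perturbation, w$genesets, a, b)$score
  members <- cbpln:::set_list(w$genesets)[[a]]
  for (g in members[1:5]) {
    pt2 <- w$perturbation
    i <- match(g, pt2$gene)
    pt2$score[i] <- pt2$score[i] + 5
    expect_gte(
      contextual_linkage_score(w$network, pt2, w$genesets, a, b)$score,
      base
    )
  }
  for (e in c(1L, 7L, nrow(w$network))) {
    net2 <- w$network
    net2$weight[e] <- net2$weight[e] * 3
    expect_gte(
      contextual_linkage_score(net2, w$perturbation, w$genesets, a, b)$score,
      base
    )
  }
})
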