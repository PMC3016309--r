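test_that("fixture generation is deterministic and satisfies network invariants", {
  fx1 <- generate_fixture(seed = 3)
  fx2 <- generate_fixture(seed = 3)
  expect_identical(fx1$network, fx2$network)
  expect_identical(cbpln:::set_list(fx1$gene_sets), cbpln:::set_list(fx2$gene_sets))
  expect_identical(fx1$perturbation$pvalue, fx2$perturbation$pvalue)
  expect_identical(fx1$truth$planted_links, fx2$truth$planted_links)

  net <- fx1$network
  expect_false(any(net$from == net$to))
  expect_false(any(duplicated(paste(net$from, net$to))))
  expect_true(all(net$weight > 0 & net$weight <= 1))
  expect_true(all(net$from < net$to))

  # different seed, different world
  fx3 <- generate_fixture(seed = 4)
  expect_false(identical(fx1$network, fx3$network))
})

test_that("planted pairs meet the interactor guarantee in both orientations", {
  fx <- generate_fixture(seed = 9)
  restricted <- restrict_to_annotated(fx$network, fx$gene_sets)
  for (i in seq_len(nrow(fx$truth$planted_links))) {
    a <- fx$truth$planted_links$source[i]
    b <- fx$truth$planted_links$target[i]
    expect_gte(
      length(neighbor_sets(restricted, fx$gene_sets, a, b)$n_ab),
      fx$truth$params$min_interactors
    )
  }
  # both orientations of every planted pair are recorded as truth
  expect_equal(nrow(fx$truth$planted_links), 2L * nrow(fx$truth$planted_pairs))
})

test_that("a saturated planted block links every exclusive target gene", {
  params <- fixture_params(
    n_genes = 80, n_processes = 2, size_range = c(20, 20),
    bg_edge_prob = 0, planted_edge_prob = 1, n_planted = 1,
    min_interactors = 10
  )
  fx <- generate_fixture(params, seed = 2)
  restricted <- restrict_to_annotated(fx$network, fx$gene_sets)
  ns <- neighbor_sets(restricted, fx$gene_sets, "P01", "P02")
  # disjoint partition: |N(A,B)| equals the full target set size
  expect_equal(length(ns$n_ab), 20L)
})

test_that("a degenerate generator yields a pure null fixture", {
  params <- fixture_params(
    n_genes = 150, n_processes = 4, size_range = c(15, 20),
    bg_edge_prob = 0.05, n_planted = 0
  )
  fx <- generate_fixture(params, seed = 8)
  expect_equal(nrow(fx$truth$planted_pairs), 0L)
  expect_length(fx$truth$perturbed_genes, 0L)
  # all p-values exchangeable uniforms
  expect_gt(stats::ks.test(fx$perturbation$pvalue, "punif")$p.value, 0.01)
})

test_that("fixtures round-trip through the on-disk input formats", {
  fx <- generate_fixture(
    fixture_params(
      n_genes = 100, n_processes = 3,
      size_range = c(10, 14), bg_edge_prob = 0.04, n_planted = 1,
      min_interactors = 3
    ),
    seed = 5
  )
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  net <- read_network(file.path(dir, "network.tsv"))
  gs <- read_gene_sets(file.path(dir, "gene_sets.gmt"))
  pt <- read_perturbation(file.path(dir, "perturbation.tsv"))
  expect_equal(net$from, fx$network$from)
  expect_equal(net$weight, fx$network$weight)
  expect_equal(cbpln:::set_list(gs), cbpln:::set_list(fx$gene_sets))
  expect_equal(pt$pvalue, fx$perturbation$pvalue)
})

test_that("recovery metrics follow the set algebra of called vs planted", {
  planted <- tibble::tibble(source = c("A", "B"), target = c("B", "C"))
  truth <- structure(list(planted_links = planted), class = "fixture_truth")
  cand <- expand.grid(
    source = LETTERS[1:4], target = LETTERS[1:4],
    stringsAsFactors = FALSE
  )
  cand <- cand[cand$source != cand$target, ] # 12 ordered pairs
  # called == planted
  r <- evaluate_recovery(planted, truth, cand)
  expect_equal(r$power, 1.0)
  expect_equal(r$false_positive_fraction, 0.0)
  # nothing called
  r0 <- evaluate_recovery(planted[0, ], truth, cand)
  expect_equal(r0$power, 0.0)
  expect_equal(r0$false_positive_fraction, 0.0)
  # one hit, one miss, one false call
  called <- tibble::tibble(source = c("A", "C"), target = c("B", "A"))
  r1 <- evaluate_recovery(called, truth, cand)
  expect_equal(r1$power, 0.5)
  expect_equal(r1$false_positive_fraction, 1 / 10)
  # guard rails
  expect_error(
    evaluate_recovery(tibble::tibble(source = "Z", target = "Q"), truth, cand),
    "subset"
  )
  empty_truth <- structure(list(planted_links = planted[0, ]), class = "fixture_truth")
  expect_error(evaluate_recovery(planted[0, ], empty_truth, cand), "power")
})

test_that("statistical power rises with the planted effect", {
  run_power <- function(edge_prob) {
    fx <- generate_fixture(
      fixture_params(
        n_genes = 150, n_processes = 4, size_range = c(12, 16),
        bg_edge_prob = 0.02, planted_edge_prob = edge_prob, n_planted = 1,
        min_interactors = 2
      ),
      seed = 17
    )
    res <- compute_cbpln(
      fx$network, fx$gene_sets, fx$perturbation,
      cbpln_config(permutations = 200, min_interactors = 2, seed = 5, tests = "geneset")
    )
    evaluate_recovery(
      res$graph[, c("source", "target")], fx$truth,
      tidy(res)[, c("source", "target")]
    )$power
  }
  expect_gte(run_power(0.5), run_power(0.05))
})
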