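# The worked toy used across modules: two 3-gene processes sharing gene c1,
# four weighted interactions, and base-10 perturbation scores 2,1,3,2,4.
toy_network <- function() {
  fin_network(data.frame(
    from = c("a1", "a2", "a2", "a1"),
    to = c("b1", "b1", "b2", "c1"),
    weight = c(0.8, 0.5, 1.0, 0.9)
  ))
}

toy_genesets <- function() {
  gene_sets(list(A = c("a1", "a2", "c1"), B = c("b1", "b2", "c1")))
}

toy_perturbation <- function() {
  perturbation(data.frame(
    gene = c("a1", "a2", "b1", "b2", "c1"),
    pvalue = 10^-c(2, 1, 3, 2, 4)
  ))
}

# Small random world for property tests: n genes in k disjoint sets,
# Erdos-Renyi background edges, uniform weights and p-values.
random_world <- function(seed, n_genes = 60, n_sets = 4, set_size = 12,
                         edge_prob = 0.08, unit = FALSE) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    members <- split(
      genes[seq_len(n_sets * set_size)],
      rep(seq_len(n_sets), each = set_size)
    )
    names(members) <- sprintf("S%02d", seq_len(n_sets))
    gs <- gene_sets(members)
    pairs <- utils::combn(n_genes, 2)
    hit <- stats::runif(ncol(pairs)) < edge_prob
    net <- fin_network(data.frame(
      from = genes[pairs[1, hit]], to = genes[pairs[2, hit]],
      weight = if (unit) 1 else stats::runif(sum(hit), 0.3, 1)
    ))
    pt <- perturbation(data.frame(
      gene = genes,
      pvalue = if (unit) rep(0.1, n_genes) else stats::runif(n_genes)
    ))
    list(network = net, genesets = gs, perturbation = pt)
  })
}

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

derive_seed_for_test <- function(a, b) {
  cbpln:::derive_seed(12345L, a, b)
}
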