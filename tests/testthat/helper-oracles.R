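# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and stats::phyper / p.adjust / fisher.test) so that agreement is
# a genuine cross-check, not a tautology.

# P(X >= observed) by exhaustive enumeration of all C(population, draws)
# subsets of a labeled population with `successes` marked elements.
oracle_hyper_tail <- function(population, successes, draws, observed) {
  if (draws == 0 || population == 0) {
    return(if (observed <= 0) 1 else 0)
  }
  marked <- seq_len(successes)
  subsets <- utils::combn(population, draws)
  hits <- colSums(matrix(subsets %in% marked, nrow = draws))
  mean(hits >= observed)
}

# Naive double-loop contextual linkage score over all gene pairs.
oracle_score <- function(network, perturbation, genesets, a, b) {
  ga <- unique(genesets$gene[genesets$set == a])
  gb <- unique(genesets$gene[genesets$set == b])
  s <- function(g) {
    i <- match(g, perturbation$gene)
    if (is.na(i)) 0 else perturbation$score[i]
  }
  w <- function(x, y) {
    hit <- (network$from == x & network$to == y) | (network$from == y & network$to == x)
    if (any(hit)) max(network$weight[hit]) else NA_real_
  }
  nodes <- sort(unique(c(network$from, network$to)))
  total <- 0
  for (v in nodes) {
    if (v %in% ga || !(v %in% gb)) next
    f <- 0
    seen_neighbor <- FALSE
    for (u in nodes) {
      if (!(u %in% ga) || u == v) next
      wv <- w(u, v)
      if (is.na(wv)) next
      seen_neighbor <- TRUE
      f <- max(f, wv * s(u))
    }
    if (seen_neighbor) total <- total + s(v) * f
  }
  total
}

# Textbook BH step-up with explicit cumulative minimum from the largest p.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# One-sided Fisher p for a 2x2 table by summing hypergeometric point masses
# (computed from choose(), not dhyper) for the top-left cell and larger.
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  b <- tab[1, 2]
  c_ <- tab[2, 1]
  d <- tab[2, 2]
  n <- a + b + c_ + d
  k1 <- a + b # row 1 total
  m1 <- a + c_ # col 1 total
  xs <- max(0, k1 + m1 - n):min(k1, m1)
  mass <- choose(m1, xs) * choose(n - m1, k1 - xs) / choose(n, k1)
  sum(mass[xs >= a])
}

# Exact law of the gene-set-randomization statistic under unit scores and
# weights: P(|N(A) ^ pi(G_B)| > observed) for a uniform label permutation,
# computed from first principles (ratio of binomial coefficients).
oracle_perm_tail_strict <- function(n_u, n_na, n_b, observed) {
  xs <- max(0, n_na + n_b - n_u):min(n_na, n_b)
  mass <- choose(n_na, xs) * choose(n_u - n_na, n_b - xs) / choose(n_u, n_b)
  sum(mass[xs > observed])
}
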