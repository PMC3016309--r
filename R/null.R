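# ---- randomizers ----------------------------------------------------------

#' Permute annotation labels on the gene-process bipartite graph
#'
#' Applies one uniform random permutation to the gene labels of the
#' gene-annotation incidence structure. Every process keeps its size and every
#' group of processes co-annotates exactly as many genes as before; only the
#' identity of the annotated genes changes. This is the randomization behind
#' the gene-set null model.
#'
#' @param genesets A [gene_sets] collection.
#' @param seed Integer seed (required; the permutation is deterministic given
#'   the seed).
#' @return A [gene_sets] collection with permuted gene labels.
#' @export
permute_annotations <- function(genesets, seed) {
  u <- gene_universe(genesets)
  perm <- withr::with_seed(seed, sample(u))
  names(perm) <- u
  gene_sets(
    tibble::tibble(set = genesets$set, gene = unname(perm[genesets$gene])),
    descriptions = attr(genesets, "descriptions")
  )
}

#' Degree-preserving edge-swap randomization
#'
#' Rewires the network with `swap_multiplier * |E|` pairwise edge-swap
#' attempts. Each attempt picks two distinct edges `(u,v)` and `(x,y)`,
#' chooses with equal probability the candidate pair `{(u,y),(x,v)}` or
#' `{(u,x),(v,y)}`, and applies it only if neither candidate edge already
#' exists or would be a self-loop. Node set, every node degree and the
#' multiset of edge weights are preserved exactly (each weight travels with
#' its surviving edge slot).
#'
#' @param network A [fin_network].
#' @param swap_multiplier Swap attempts per edge (Q); `Q = 0` returns the
#'   network unchanged.
#' @param seed Integer seed.
#' @return A rewired [fin_network].
#' @export
swap_edges <- function(network, swap_multiplier = 100, seed) {
  if (swap_multiplier < 0) stop("`swap_multiplier` must be >= 0.", call. = FALSE)
  nodes <- network_nodes(network)
  ui <- match(network$from, nodes)
  vi <- match(network$to, nodes)
  res <- withr::with_seed(
    seed,
    swap_edges_impl(ui, vi, length(nodes), swap_multiplier)
  )
  fin_network(data.frame(
    from = nodes[res$from], to = nodes[res$to], weight = network$weight
  ))
}

# ---- null distributions ---------------------------------------------------

new_null_distribution <- function(values, generator, seed, normalize) {
  structure(
    list(values = values, generator = generator, seed = seed, normalize = normalize),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", length(x$values), " replicates (",
    x$generator, " randomization",
    if (x$normalize) ", normalized", ")\n",
    sep = ""
  )
  print(summary(x$values))
  invisible(x)
}

# contribution vectors over the universe for one source process:
#   contrib[v]    = s(v) * f_A(v)          for v in N(A), else 0
#   contrib_bg[v] = sbar^2 * wmax_A(v)     for v in N(A), else 0
#   f_map[v]      = f_A(v)                 for v in N(A), else 0
contribution_vectors <- function(idx, source, sbar) {
  in_a <- membership_flags(idx$n_u, idx$sets[[source]])
  prof <- source_profile(idx$u2, idx$v2, idx$w2, in_a, idx$s)
  contrib <- numeric(idx$n_u)
  contrib[prof$ids] <- idx$s[prof$ids] * prof$f
  contrib_bg <- numeric(idx$n_u)
  contrib_bg[prof$ids] <- sbar^2 * prof$wmax
  f_map <- numeric(idx$n_u)
  f_map[prof$ids] <- prof$f
  in_na <- membership_flags(idx$n_u, prof$ids)
  list(contrib = contrib, contrib_bg = contrib_bg, f_map = f_map, in_na = in_na)
}

# Core gene-set randomization loop for a single ordered pair on an index.
geneset_null_values <- function(idx, sbar, source, target, permutations, seed,
                                normalize, randomize) {
  a_ids <- idx$sets[[source]]
  b_ids <- idx$sets[[target]]
  withr::with_seed(seed, {
    if (randomize == "target") {
      cv <- contribution_vectors(idx, source, sbar)
      vapply(seq_len(permutations), function(r) {
        perm <- sample.int(idx$n_u)
        b_r <- perm[b_ids]
        s_val <- sum(cv$contrib[b_r])
        if (normalize) s_val - sum(cv$contrib_bg[b_r]) else s_val
      }, numeric(1))
    } else {
      sbar_vec <- rep(sbar, idx$n_u)
      in_b <- membership_flags(idx$n_u, b_ids)
      vapply(seq_len(permutations), function(r) {
        perm <- sample.int(idx$n_u)
        in_a <- membership_flags(idx$n_u, perm[a_ids])
        prof <- source_profile(idx$u2, idx$v2, idx$w2, in_a, idx$s)
        linked <- in_b[prof$ids]
        s_val <- sum(idx$s[prof$ids[linked]] * prof$f[linked])
        if (!normalize) {
          s_val
        } else {
          s_val - sum(sbar^2 * prof$wmax[linked])
        }
      }, numeric(1))
    }
  })
}

#' Gene-set randomization null distribution for one link
#'
#' Replicates the contextual linkage score under random annotation labels:
#' each replicate permutes the gene labels of the bipartite annotation graph
#' (see [permute_annotations()]) and replaces the randomized set — by default
#' the target process — while the other set and the network stay fixed. With
#' normalization, each replicate's background score is recomputed under its
#' own randomized annotations.
#'
#' @param network A [fin_network].
#' @param perturbation A [perturbation] table.
#' @param genesets A [gene_sets] collection.
#' @param source,target Process identifiers.
#' @param permutations Number of replicates R.
#' @param seed Integer seed.
#' @param normalize Record normalized scores (`S - S_bg`) instead of raw ones.
#' @param randomize Which side of the link to randomize: `"target"` (default)
#'   or `"source"`.
#' @return A `null_distribution` object.
#' @export
geneset_null_distribution <- function(network, perturbation, genesets, source,
                                      target, permutations = 1000, seed,
                                      normalize = TRUE,
                                      randomize = c("target", "source")) {
  randomize <- match.arg(randomize)
  if (permutations < 1) stop("`permutations` must be >= 1.", call. = FALSE)
  idx <- cbpln_index(network, genesets, perturbation)
  sbar <- mean_measured_score(idx)
  if (!source %in% names(idx$sets)) stop("unknown process: ", source, call. = FALSE)
  if (!target %in% names(idx$sets)) stop("unknown process: ", target, call. = FALSE)
  values <- geneset_null_values(
    idx, sbar, source, target, permutations, seed,
    normalize, randomize
  )
  new_null_distribution(values, "geneset", seed, normalize)
}

#' Network randomization null distribution for one link
#'
#' Replicates the contextual linkage score over degree-preserving edge-swap
#' randomizations of the interaction network (see [swap_edges()]), holding
#' annotations and perturbation fixed. Each replicate rewires the network
#' afresh from the observed one and recomputes the (optionally normalized)
#' score.
#'
#' @inheritParams geneset_null_distribution
#' @param swap_multiplier Swap attempts per edge for each replicate.
#' @return A `null_distribution` object.
#' @export
network_null_distribution <- function(network, perturbation, genesets, source,
                                      target, permutations = 1000,
                                      swap_multiplier = 100, seed,
                                      normalize = TRUE) {
  if (permutations < 1) stop("`permutations` must be >= 1.", call. = FALSE)
  idx <- cbpln_index(network, genesets, perturbation)
  if (!source %in% names(idx$sets)) stop("unknown process: ", source, call. = FALSE)
  if (!target %in% names(idx$sets)) stop("unknown process: ", target, call. = FALSE)
  sbar <- mean_measured_score(idx)
  stat <- network_null_matrix(
    idx,
    pairs = data.frame(source = source, target = target),
    permutations = permutations, swap_multiplier = swap_multiplier,
    seed = seed, normalize = normalize, sbar = sbar
  )
  new_null_distribution(as.numeric(stat[1L, ]), "network", seed, normalize)
}

# Shared machinery: R edge-swapped replicates of the indexed network, scored
# for every requested ordered pair in compiled code. Returns a pairs x R
# matrix. Replicate seeds derive from (seed, "swap", r) so results do not
# depend on pair or replicate evaluation order.
network_null_matrix <- function(idx, pairs, permutations, swap_multiplier,
                                seed, normalize, sbar) {
  set_idx <- match(names(idx$sets), names(idx$sets))
  src_i <- match(pairs$source, names(idx$sets))
  tgt_i <- match(pairs$target, names(idx$sets))
  stat <- matrix(NA_real_, nrow = nrow(pairs), ncol = permutations)
  for (r in seq_len(permutations)) {
    stat[, r] <- withr::with_seed(
      derive_seed(seed, "swap", r),
      swap_and_score_impl(
        idx$edge_u, idx$edge_v, idx$edge_w, idx$n_u, swap_multiplier,
        idx$sets, src_i, tgt_i, idx$s, sbar, normalize
      )
    )
  }
  stat
}

# ---- empirical p-values and multiple testing ------------------------------

#' Empirical p-value from a null distribution
#'
#' The fraction of null replicates strictly larger than the observed value.
#' The strict rule can return exactly 0 when the observed score exceeds every
#' replicate; set `pseudocount = TRUE` for the (count + 1) / (R + 1) variant
#' that is bounded away from 0.
#'
#' @param observed Observed statistic.
#' @param null A `null_distribution` object or numeric vector of replicates.
#' @param pseudocount Use the add-one estimator instead of the plain fraction.
#' @return A p-value in `[0, 1]`.
#' @export
empirical_pvalue <- function(observed, null, pseudocount = FALSE) {
  values <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(values) == 0L) stop("empty null distribution.", call. = FALSE)
  n_larger <- sum(values > observed)
  if (pseudocount) (n_larger + 1) / (length(values) + 1) else n_larger / length(values)
}

#' Monotone Benjamini-Hochberg adjustment
#'
#' Standard BH step-up adjusted p-values, monotone non-decreasing in the raw
#' p-value ordering and capped at 1; the output order matches the input order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust_monotone <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
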