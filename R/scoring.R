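# ---- internal indexed representation -------------------------------------
#
# All heavy computation runs on integer indices into the annotation universe
# U (position in sort(unique(genes))). The index carries the network restricted
# to U as bidirectional integer arrays, per-process membership, and the
# perturbation score vector over U (0 for genes without a measured p-value).

cbpln_index <- function(network, genesets, perturbation = NULL) {
  u <- gene_universe(genesets)
  net <- restrict_to_annotated(network, genesets)
  ui <- match(net$from, u)
  vi <- match(net$to, u)
  sets <- lapply(set_list(genesets), function(m) sort(match(m, u)))
  s <- if (is.null(perturbation)) rep(0, length(u)) else perturbation_scores(perturbation, u)
  measured <- if (is.null(perturbation)) logical(length(u)) else u %in% perturbation$gene
  list(
    universe = u, n_u = length(u),
    edge_u = ui, edge_v = vi, edge_w = net$weight,
    u2 = c(ui, vi), v2 = c(vi, ui), w2 = c(net$weight, net$weight),
    sets = sets, s = s, measured = measured,
    network = net
  )
}

# For one source process: N(A) as sorted indices, with
#   f(v)    = max over A-annotated neighbors u of w(u,v) * s(u)
#   wmax(v) = max over A-annotated neighbors u of w(u,v)
# computed by a sort + first-of-group sweep (vectorized grouped maximum).
source_profile <- function(u2, v2, w2, in_a, s) {
  keep <- in_a[u2] & !in_a[v2]
  vv <- v2[keep]
  if (length(vv) == 0L) {
    return(list(ids = integer(0), f = numeric(0), wmax = numeric(0)))
  }
  val <- w2[keep] * s[u2[keep]]
  wv <- w2[keep]
  o <- order(vv, -val)
  first <- !duplicated(vv[o])
  ids <- vv[o][first]
  f <- val[o][first]
  o2 <- order(vv, -wv)
  wmax <- wv[o2][!duplicated(vv[o2])]
  list(ids = ids, f = f, wmax = wmax)
}

membership_flags <- function(n_u, ids) {
  out <- logical(n_u)
  out[ids] <- TRUE
  out
}

mean_measured_score <- function(idx) {
  if (!any(idx$measured)) {
    stop("no gene in the universe has a measured p-value.", call. = FALSE)
  }
  mean(idx$s[idx$measured])
}

# ---- exported scoring operations -----------------------------------------

#' Contribution of the source-process neighborhood to one gene
#'
#' For a gene `v`, the source-side contribution `f_A(v)` is the maximum of
#' `w(u, v) * s(u)` over neighbors `u` of `v` annotated with the source
#' process: one strong, high-confidence interaction with a strongly perturbed
#' source gene suffices. Genes with no source-annotated neighbor contribute 0.
#'
#' @param network A [fin_network].
#' @param perturbation A [perturbation] table.
#' @param genesets A [gene_sets] collection.
#' @param source Process identifier.
#' @param gene Gene identifier (must be a network node).
#' @return `f_A(v)`, a non-negative real.
#' @export
neighbor_contribution <- function(network, perturbation, genesets, source, gene) {
  if (!gene %in% network_nodes(network)) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  ga <- set_members(genesets, source)
  u2 <- c(network$from, network$to)
  v2 <- c(network$to, network$from)
  w2 <- c(network$weight, network$weight)
  keep <- v2 == gene & (u2 %in% ga)
  if (!any(keep)) {
    return(0)
  }
  max(w2[keep] * perturbation_scores(perturbation, u2[keep]))
}

#' Contextual linkage score between two processes
#'
#' The directed score
#' `S(A, B) = sum over v in N(A,B) of s(v) * f_A(v)`:
#' each target-annotated neighbor of the source set contributes its own
#' perturbation times the best confidence-weighted perturbation among its
#' source-annotated neighbors. With all scores and weights equal to 1 the sum
#' collapses to `|N(A,B)|`, the context-free interactor count.
#'
#' @inheritParams neighbor_contribution
#' @param target Process identifier.
#' @return A list with `score` (the scalar `S(A,B)`) and `contributions`, a
#'   tibble (`gene`, `score`, `f_source`, `product`) with one row per gene of
#'   `N(A,B)`.
#' @examples
#' net <- fin_network(data.frame(
#'   from = c("a1", "a2", "a2", "a1"), to = c("b1", "b1", "b2", "c1"),
#'   weight = c(0.8, 0.5, 1.0, 0.9)
#' ))
#' gs <- gene_sets(list(A = c("a1", "a2", "c1"), B = c("b1", "b2", "c1")))
#' pt <- perturbation(data.frame(
#'   gene = c("a1", "a2", "b1", "b2", "c1"),
#'   pvalue = 10^-c(2, 1, 3, 2, 4)
#' ))
#' contextual_linkage_score(net, pt, gs, "A", "B")$score # 6.8
#' @export
contextual_linkage_score <- function(network, perturbation, genesets, source, target) {
  idx <- cbpln_index(network, genesets, perturbation)
  score_pair(idx, source, target, idx$s)
}

score_pair <- function(idx, source, target, s) {
  if (!source %in% names(idx$sets)) stop("unknown process: ", source, call. = FALSE)
  if (!target %in% names(idx$sets)) stop("unknown process: ", target, call. = FALSE)
  in_a <- membership_flags(idx$n_u, idx$sets[[source]])
  in_b <- membership_flags(idx$n_u, idx$sets[[target]])
  prof <- source_profile(idx$u2, idx$v2, idx$w2, in_a, s)
  linked <- in_b[prof$ids]
  genes <- idx$universe[prof$ids[linked]]
  sv <- s[prof$ids[linked]]
  fv <- prof$f[linked]
  list(
    score = sum(sv * fv),
    contributions = tibble::tibble(
      gene = genes, score = sv, f_source = fv, product = sv * fv
    )
  )
}

#' Background score under average perturbation
#'
#' The contextual linkage score recomputed after giving every gene the mean
#' perturbation score, the mean being taken over genes of the universe with a
#' measured p-value. It is the score the link would attain if expression
#' carried no gene-specific information; subtracting it (see
#' [normalized_score()]) removes the purely topological part of the score.
#'
#' @inheritParams contextual_linkage_score
#' @return The scalar background score `S_bg`.
#' @export
background_score <- function(network, perturbation, genesets, source, target) {
  idx <- cbpln_index(network, genesets, perturbation)
  sbar <- mean_measured_score(idx)
  score_pair(idx, source, target, rep(sbar, idx$n_u))$score
}

#' Normalized contextual linkage score
#'
#' `S_norm = S - S_bg`; may be negative when a link scores below what average
#' perturbation alone would produce.
#'
#' @param score Observed score `S`.
#' @param background Background score `S_bg`.
#' @return `S - S_bg`.
#' @export
normalized_score <- function(score, background) {
  score - background
}
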