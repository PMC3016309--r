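#' Neighborhood sets of a process pair
#'
#' `N(A)` is the set of genes adjacent in the network to at least one gene
#' annotated with the source process but not annotated with it themselves;
#' `N(A,B)` is the subset of `N(A)` additionally annotated with the target
#' process. These neighborhoods are the raw material of both the context-free
#' baseline and the contextual score. `N(A,A)` is empty by construction.
#'
#' @param network A [fin_network] (restricted to annotated genes for the
#'   canonical analysis; the function itself works on any network).
#' @param genesets A [gene_sets] collection.
#' @param source,target Process identifiers.
#' @return A list with character vectors `n_a` and `n_ab`.
#' @export
neighbor_sets <- function(network, genesets, source, target) {
  ga <- set_members(genesets, source)
  gb <- set_members(genesets, target)
  u2 <- c(network$from, network$to)
  v2 <- c(network$to, network$from)
  keep <- (u2 %in% ga) & !(v2 %in% ga)
  n_a <- sort(unique(v2[keep]))
  list(n_a = n_a, n_ab = n_a[n_a %in% gb])
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= observed)` where `X` counts successes among `draws` draws without
#' replacement from a population containing `successes` successes.
#'
#' @param population,successes,draws,observed Non-negative integer counts with
#'   `successes <= population`, `draws <= population` and
#'   `observed <= min(successes, draws)`.
#' @return The tail probability, in (0, 1].
#' @examples
#' hypergeometric_tail(10, 4, 3, 2) # 40/120
#' @export
hypergeometric_tail <- function(population, successes, draws, observed) {
  counts <- c(population, successes, draws, observed)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers.", call. = FALSE)
  }
  if (successes > population || draws > population) {
    stop("`successes` and `draws` must not exceed `population`.", call. = FALSE)
  }
  if (observed > min(successes, draws)) {
    stop("`observed` exceeds min(successes, draws).", call. = FALSE)
  }
  stats::phyper(observed - 1, successes, population - successes, draws,
    lower.tail = FALSE
  )
}

#' Context-free link p-value (hypergeometric baseline)
#'
#' The original biological-process linkage test: is the number of source-set
#' neighbors annotated with the target process, `|N(A,B)|`, surprisingly large
#' for `|N(A)|` genes drawn uniformly from the universe? The population
#' convention used here excludes the source set: draws are taken from
#' `U \ G_A` (members of `N(A)` can never be annotated with the source, so the
#' sampling frame excludes them too). This convention is deliberate and fixed;
#' see the methods vignette.
#'
#' @inheritParams neighbor_sets
#' @return The hypergeometric tail p-value.
#' @export
bpln_link_pvalue <- function(network, genesets, source, target) {
  ga <- set_members(genesets, source)
  gb <- set_members(genesets, target)
  u <- gene_universe(genesets)
  ns <- neighbor_sets(network, genesets, source, target)
  hypergeometric_tail(
    population = length(setdiff(u, ga)),
    successes = length(setdiff(gb, ga)),
    draws = length(ns$n_a),
    observed = length(ns$n_ab)
  )
}

#' Build the context-free process linkage network
#'
#' Evaluates every ordered process pair whose interactor count `|N(A,B)|`
#' reaches `min_interactors`, computes the hypergeometric link p-value,
#' adjusts with Benjamini-Hochberg across the evaluated pairs, and flags links
#' with adjusted p-value at or below `alpha`. The output is directed: A -> B
#' and B -> A are judged independently and may disagree.
#'
#' @inheritParams neighbor_sets
#' @param alpha Significance cutoff on the BH-adjusted p-value.
#' @param min_interactors Minimum `|N(A,B)|` for a pair to be evaluated.
#' @return A tibble with one row per evaluated ordered pair: `source`,
#'   `target`, `n_neighbors`, `n_linked`, `bpln_p`, `q_bpln`, `significant`.
#' @export
build_bpln <- function(network, genesets, alpha = 0.01, min_interactors = 10) {
  procs <- process_ids(genesets)
  if (length(procs) < 2L) stop("need at least 2 processes.", call. = FALSE)
  net <- restrict_to_annotated(network, genesets)
  pairs <- expand.grid(
    target = procs, source = procs,
    stringsAsFactors = FALSE
  )[, c("source", "target")]
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rows <- purrr::pmap(pairs, function(source, target) {
    ns <- neighbor_sets(net, genesets, source, target)
    tibble::tibble(
      source = source, target = target,
      n_neighbors = length(ns$n_a), n_linked = length(ns$n_ab)
    )
  })
  links <- dplyr::bind_rows(rows)
  links <- links[links$n_linked >= min_interactors, , drop = FALSE]
  if (nrow(links) == 0L) {
    warning("no process pair reaches min_interactors = ", min_interactors)
    return(tibble::tibble(
      source = character(), target = character(),
      n_neighbors = integer(), n_linked = integer(),
      bpln_p = numeric(), q_bpln = numeric(), significant = logical()
    ))
  }
  links$bpln_p <- purrr::map2_dbl(
    links$source, links$target,
    function(a, b) bpln_link_pvalue(net, genesets, a, b)
  )
  links$q_bpln <- bh_adjust_monotone(links$bpln_p)
  links$significant <- links$q_bpln <= alpha
  tibble::as_tibble(links)
}
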