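#' Pipeline configuration
#'
#' Collects every tunable of the contextual linkage pipeline with the
#' canonical defaults: 10,000 permutation replicates, 100 swap attempts per
#' edge, FDR 0.01, at least 10 exclusive interactors per evaluated pair,
#' base-10 perturbation scores, raw interaction weights kept at >= 500 and
#' rescaled by 1/1000, normalization on, and both hypothesis tests.
#'
#' @param permutations Replicates R for each empirical null.
#' @param swap_multiplier Swap attempts per edge (Q) for network
#'   randomization.
#' @param fdr_alpha Cutoff on BH-adjusted link p-values.
#' @param min_interactors Minimum `|N(A,B)|` for a pair to enter the analysis
#'   (and the BH family).
#' @param log_base Base for perturbation scores.
#' @param weight_scale,weight_min Raw-weight rescaling divisor and threshold
#'   (used by [read_network()]; recorded here for provenance).
#' @param normalize Test the normalized score `S - S_bg` instead of `S`.
#' @param tests Character subset of `c("geneset", "network")`.
#' @param seed Master seed; every random stream in the pipeline derives from
#'   it deterministically.
#' @param pvalue_floor Replacement for zero expression p-values.
#' @param randomize_set Which side the gene-set randomization replaces:
#'   `"target"` (default) or `"source"`.
#' @param pseudocount Use the (count+1)/(R+1) empirical p-value estimator.
#' @param share_null Share randomization replicates across ordered pairs
#'   (default). Per-pair independent streams cost a full randomization per
#'   pair per replicate; the shared mode is distributionally identical for
#'   each pair.
#' @return A list of class `cbpln_config`.
#' @export
cbpln_config <- function(permutations = 10000, swap_multiplier = 100,
                         fdr_alpha = 0.01, min_interactors = 10,
                         log_base = 10, weight_scale = 1000, weight_min = 500,
                         normalize = TRUE, tests = c("geneset", "network"),
                         seed = 1L, pvalue_floor = 1e-300,
                         randomize_set = c("target", "source"),
                         pseudocount = FALSE, share_null = TRUE) {
  randomize_set <- match.arg(randomize_set)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(
    permutations >= 1, swap_multiplier >= 0,
    fdr_alpha > 0, fdr_alpha <= 1, min_interactors >= 0, log_base > 1
  )
  structure(
    list(
      permutations = as.integer(permutations),
      swap_multiplier = swap_multiplier,
      fdr_alpha = fdr_alpha,
      min_interactors = as.integer(min_interactors),
      log_base = log_base, weight_scale = weight_scale,
      weight_min = weight_min, normalize = normalize, tests = tests,
      seed = as.integer(seed), pvalue_floor = pvalue_floor,
      randomize_set = randomize_set, pseudocount = pseudocount,
      share_null = share_null
    ),
    class = "cbpln_config"
  )
}

#' Compute the contextual process linkage network
#'
#' Runs the full pipeline for one biological contrast: restricts the network
#' to annotated genes, enumerates ordered process pairs, drops pairs with
#' fewer than `min_interactors` target-exclusive interactors, computes the
#' contextual linkage score with its background and normalization, runs the
#' configured empirical null models, adjusts each test with
#' Benjamini-Hochberg across the evaluated pairs, and assembles the directed
#' linkage graph from the links whose adjusted p-value is at or below
#' `fdr_alpha` under every configured test.
#'
#' @param network A [fin_network].
#' @param genesets A [gene_sets] collection (at least 2 processes).
#' @param perturbation A [perturbation] table for the contrast.
#' @param config A [cbpln_config].
#' @return An object of class `cbpln_result`: list with `links` (tibble of
#'   all evaluated ordered pairs and their statistics, including a
#'   `contributions` list-column), `graph` (tibble of significant directed
#'   links), and `config`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
compute_cbpln <- function(network, genesets, perturbation,
                          config = cbpln_config()) {
  stopifnot(inherits(config, "cbpln_config"))
  procs <- process_ids(genesets)
  if (length(procs) < 2L) stop("need at least 2 processes.", call. = FALSE)
  idx <- cbpln_index(network, genesets, perturbation)
  sbar <- mean_measured_score(idx)

  pairs <- expand.grid(target = procs, source = procs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL

  # observed profiles per source process
  profs <- lapply(procs, function(a) contribution_vectors(idx, a, sbar))
  names(profs) <- procs
  in_b <- lapply(idx$sets, function(ids) membership_flags(idx$n_u, ids))

  links <- dplyr::bind_rows(purrr::pmap(pairs, function(source, target) {
    cv <- profs[[source]]
    b_ids <- idx$sets[[target]]
    sel <- b_ids[cv$in_na[b_ids]]
    s_obs <- sum(cv$contrib[b_ids])
    s_bg <- sum(cv$contrib_bg[b_ids])
    tibble::tibble(
      source = source, target = target,
      n_neighbors = sum(cv$in_na), n_linked = length(sel),
      score = s_obs, background = s_bg, normalized = s_obs - s_bg
    )
  }))
  links <- links[links$n_linked >= config$min_interactors, , drop = FALSE]
  if (nrow(links) == 0L) {
    warning("no process pair reaches min_interactors = ", config$min_interactors)
    empty <- links
    return(structure(
      list(links = empty, graph = empty, config = config),
      class = "cbpln_result"
    ))
  }

  observed <- if (config$normalize) links$normalized else links$score

  # hypergeometric baseline p-value (population convention: U \ G_A)
  links$bpln_p <- purrr::map2_dbl(links$source, links$target, function(a, b) {
    ga <- idx$sets[[a]]
    gb <- idx$sets[[b]]
    cv <- profs[[a]]
    hypergeometric_tail(
      population = idx$n_u - length(ga),
      successes = length(setdiff(gb, ga)),
      draws = sum(cv$in_na),
      observed = sum(cv$in_na[gb])
    )
  })

  links$p_geneset <- NA_real_
  links$p_network <- NA_real_
  links$q_geneset <- NA_real_
  links$q_network <- NA_real_

  if ("geneset" %in% config$tests) {
    null_g <- geneset_null_links(idx, links, profs, sbar, config)
    links$p_geneset <- vapply(seq_len(nrow(links)), function(i) {
      empirical_pvalue(observed[i], null_g[i, ], pseudocount = config$pseudocount)
    }, numeric(1))
    links$q_geneset <- bh_adjust_monotone(links$p_geneset)
  }
  if ("network" %in% config$tests) {
    if (config$share_null) {
      null_n <- network_null_matrix(
        idx,
        pairs = links[, c("source", "target")],
        permutations = config$permutations,
        swap_multiplier = config$swap_multiplier,
        seed = derive_seed(config$seed, "network"),
        normalize = config$normalize, sbar = sbar
      )
    } else {
      null_n <- do.call(rbind, lapply(seq_len(nrow(links)), function(i) {
        network_null_matrix(
          idx,
          pairs = links[i, c("source", "target")],
          permutations = config$permutations,
          swap_multiplier = config$swap_multiplier,
          seed = derive_seed(config$seed, "network", links$source[i], links$target[i]),
          normalize = config$normalize, sbar = sbar
        )
      }))
    }
    links$p_network <- vapply(seq_len(nrow(links)), function(i) {
      empirical_pvalue(observed[i], null_n[i, ], pseudocount = config$pseudocount)
    }, numeric(1))
    links$q_network <- bh_adjust_monotone(links$p_network)
  }

  links$contributions <- purrr::map2(links$source, links$target, function(a, b) {
    cv <- profs[[a]]
    b_ids <- idx$sets[[b]]
    sel <- sort(b_ids[cv$in_na[b_ids]])
    tibble::tibble(
      gene = idx$universe[sel],
      score = idx$s[sel],
      f_source = cv$f_map[sel],
      product = idx$s[sel] * cv$f_map[sel]
    )
  })

  passed <- rep(TRUE, nrow(links))
  if ("geneset" %in% config$tests) passed <- passed & links$q_geneset <= config$fdr_alpha
  if ("network" %in% config$tests) passed <- passed & links$q_network <= config$fdr_alpha
  graph <- links[passed, setdiff(names(links), "contributions"), drop = FALSE]

  structure(
    list(links = tibble::as_tibble(links), graph = tibble::as_tibble(graph),
         config = config),
    class = "cbpln_result"
  )
}

# Gene-set null for all evaluated pairs. Shared mode draws one label
# permutation per replicate and scores every pair against it; per-pair mode
# derives an independent stream per ordered pair from the master seed.
geneset_null_links <- function(idx, links, profs, sbar, config) {
  R <- config$permutations
  if (config$randomize_set == "target" && config$share_null) {
    stat <- matrix(NA_real_, nrow = nrow(links), ncol = R)
    b_ids_list <- idx$sets[links$target]
    contrib <- lapply(profs[links$source], `[[`, "contrib")
    contrib_bg <- lapply(profs[links$source], `[[`, "contrib_bg")
    withr::with_seed(derive_seed(config$seed, "geneset"), {
      for (r in seq_len(R)) {
        perm <- sample.int(idx$n_u)
        for (i in seq_len(nrow(links))) {
          b_r <- perm[b_ids_list[[i]]]
          s_val <- sum(contrib[[i]][b_r])
          stat[i, r] <- if (config$normalize) {
            s_val - sum(contrib_bg[[i]][b_r])
          } else {
            s_val
          }
        }
      }
    })
    return(stat)
  }
  rows <- lapply(seq_len(nrow(links)), function(i) {
    geneset_null_values(
      idx, sbar,
      source = links$source[i], target = links$target[i],
      permutations = R,
      seed = derive_seed(config$seed, "geneset", links$source[i], links$target[i]),
      normalize = config$normalize, randomize = config$randomize_set
    )
  })
  do.call(rbind, rows)
}

#' One-sided Fisher's exact test for link-set overlap
#'
#' Exact enrichment p-value for the top-left cell of a 2x2 contingency table
#' given its margins (the hypergeometric tail), as used to judge whether two
#' link sets share more links than chance would allow.
#'
#' @param table A 2x2 matrix (or 4 counts, row-wise) of non-negative
#'   integers.
#' @return One-sided (enrichment) exact p-value.
#' @examples
#' fisher_exact_one_sided(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)) # 17/70
#' @export
fisher_exact_one_sided <- function(table) {
  x <- if (is.matrix(table)) {
    matrix(as.numeric(table), nrow = 2)
  } else {
    matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  }
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("contingency counts must be non-negative integers.", call. = FALSE)
  }
  stats::fisher.test(x, alternative = "greater")$p.value
}

#' Compare two sets of directed links
#'
#' Computes the intersection size, the Jaccard index (intersection over
#' union, with 0/0 defined as 0), and the one-sided Fisher's exact p-value of
#' the overlap on the 2x2 table {in both, first only, second only, neither}
#' over a candidate-pair universe.
#'
#' @param first,second,candidates Data frames of ordered pairs with columns
#'   `source` and `target`; `first` and `second` must be subsets of
#'   `candidates`.
#' @return A one-row tibble: `n_first`, `n_second`, `n_intersection`,
#'   `jaccard`, `fisher_p`, and the `contingency` matrix as a list-column.
#' @export
compare_link_sets <- function(first, second, candidates) {
  key <- function(x) paste(x$source, x$target, sep = "\r")
  k1 <- unique(key(first))
  k2 <- unique(key(second))
  kc <- unique(key(candidates))
  if (!all(k1 %in% kc) || !all(k2 %in% kc)) {
    stop("`first` and `second` must be subsets of `candidates`.", call. = FALSE)
  }
  n_both <- length(intersect(k1, k2))
  n_first_only <- length(setdiff(k1, k2))
  n_second_only <- length(setdiff(k2, k1))
  n_neither <- length(kc) - n_both - n_first_only - n_second_only
  union_size <- n_both + n_first_only + n_second_only
  tab <- matrix(c(n_both, n_first_only, n_second_only, n_neither),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_second", "not_second"), c("in_first", "not_first"))
  )
  tibble::tibble(
    n_first = length(k1), n_second = length(k2), n_intersection = n_both,
    jaccard = if (union_size == 0L) 0 else n_both / union_size,
    fisher_p = fisher_exact_one_sided(tab),
    contingency = list(tab)
  )
}
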