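#' Parameters for the synthetic fixture generator
#'
#' The defaults describe the benchmark world used throughout the package's
#' validation: ~500 genes, 8 processes of 25-40 genes drawn uniformly from the
#' gene pool (expected pairwise overlap well under 20%), background
#' interactions at probability 0.01 with confidence weights uniform on
#' (0.5, 1], and 5 planted links realized as dense cross-set blocks
#' (cross-edge probability 0.3, high weights uniform on (0.8, 1]). Genes
#' incident to a planted interaction are perturbed: their expression p-values
#' are uniform on (0, 0.001); every other gene draws p uniform on (0, 1).
#' Because planted interactions are undirected and perturb both endpoints,
#' each planted link carries signal in both orientations.
#'
#' @param n_genes Number of genes in the pool.
#' @param n_processes Number of processes.
#' @param size_range Inclusive range of process sizes.
#' @param overlap_frac Fraction of each process's members drawn from a shared
#'   pool instead of the process's exclusive block (default 0: disjoint
#'   memberships, which keeps the planted truth exact; see the methods
#'   vignette).
#' @param bg_edge_prob Background edge probability per gene pair.
#' @param planted_edge_prob Cross-edge probability inside a planted block.
#' @param n_planted Number of planted (unordered) links.
#' @param weight_range Background weight bounds (after rescaling, i.e. in
#'   (0, 1]).
#' @param planted_weight_range Planted-edge weight bounds.
#' @param perturbed_p_max Upper bound of the perturbed genes' p-value
#'   distribution.
#' @param min_interactors Planted pairs are resampled until both orientations
#'   reach this many exclusive interactors.
#' @param max_retries Resampling budget per planted pair.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_genes = 500, n_processes = 8,
                           size_range = c(25, 40), overlap_frac = 0,
                           bg_edge_prob = 0.01,
                           planted_edge_prob = 0.3, n_planted = 5,
                           weight_range = c(0.5, 1),
                           planted_weight_range = c(0.8, 1),
                           perturbed_p_max = 0.001, min_interactors = 10,
                           max_retries = 20) {
  stopifnot(
    n_genes >= 1, n_processes >= 1,
    size_range[1] >= 1, size_range[2] >= size_range[1],
    overlap_frac >= 0, overlap_frac <= 0.5,
    bg_edge_prob >= 0, bg_edge_prob <= 1,
    planted_edge_prob >= 0, planted_edge_prob <= 1,
    n_planted >= 0, perturbed_p_max > 0, perturbed_p_max <= 1
  )
  structure(
    list(
      n_genes = n_genes, n_processes = n_processes, size_range = size_range,
      overlap_frac = overlap_frac,
      bg_edge_prob = bg_edge_prob, planted_edge_prob = planted_edge_prob,
      n_planted = n_planted, weight_range = weight_range,
      planted_weight_range = planted_weight_range,
      perturbed_p_max = perturbed_p_max, min_interactors = min_interactors,
      max_retries = max_retries
    ),
    class = "fixture_params"
  )
}

#' Generate a synthetic benchmark fixture with planted links
#'
#' Builds a complete, self-consistent input triple — interaction network,
#' gene set collection and perturbation table — plus the ground truth of
#' planted links, fully determined by `params` and `seed`. Planted links are
#' dense high-weight bipartite blocks between the exclusive parts of two
#' processes whose incident genes receive small expression p-values; each
#' planted pair is guaranteed at least `min_interactors` exclusive
#' interactors in both orientations (cross edges are resampled up to
#' `max_retries` times, otherwise generation fails naming the pair).
#'
#' @param params A [fixture_params] list.
#' @param seed Integer seed; the fixture is a deterministic function of
#'   (params, seed).
#' @return A list of class `cbpln_fixture` with elements `network`
#'   ([fin_network]), `gene_sets` ([gene_sets]), `perturbation`
#'   ([perturbation]) and `truth` (class `fixture_truth`: `planted_links`
#'   tibble with both orientations of each planted link, `planted_pairs`
#'   tibble of the unordered links, `params`, `seed`).
#' @export
generate_fixture <- function(params = fixture_params(), seed) {
  stopifnot(inherits(params, "fixture_params"))
  withr::with_seed(seed, generate_fixture_impl(params, seed))
}

generate_fixture_impl <- function(params, seed) {
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  procs <- sprintf("P%02d", seq_len(params$n_processes))

  size_choices <- seq(params$size_range[1], params$size_range[2])
  sizes <- if (length(size_choices) == 1L) {
    rep(size_choices, params$n_processes)
  } else {
    sample(size_choices, params$n_processes, replace = TRUE)
  }
  # partition the gene pool: one exclusive block per process, plus an optional
  # shared pool from which overlap_frac of each process's members are drawn
  n_shared_each <- round(sizes * params$overlap_frac)
  n_excl <- sizes - n_shared_each
  pool_size <- if (any(n_shared_each > 0)) max(sizes) else 0
  if (sum(n_excl) + pool_size > params$n_genes) {
    stop("n_genes too small for the requested process sizes.", call. = FALSE)
  }
  shuffled <- sample(genes)
  shared_pool <- if (pool_size > 0) shuffled[seq_len(pool_size)] else character(0)
  rest <- if (pool_size > 0) shuffled[-seq_len(pool_size)] else shuffled
  offsets <- cumsum(c(0, n_excl[-length(n_excl)]))
  members <- lapply(seq_along(sizes), function(i) {
    own <- rest[offsets[i] + seq_len(n_excl[i])]
    extra <- if (n_shared_each[i] > 0) sample(shared_pool, n_shared_each[i]) else character(0)
    c(own, extra)
  })
  names(members) <- procs
  gs <- gene_sets(members)

  # planted links: unordered pairs of distinct processes, both orientations true
  planted_pairs <- tibble::tibble(a = character(), b = character())
  if (params$n_planted > 0) {
    all_pairs <- utils::combn(procs, 2)
    if (params$n_planted > ncol(all_pairs)) {
      stop("n_planted exceeds the number of distinct process pairs.", call. = FALSE)
    }
    pick <- sample.int(ncol(all_pairs), params$n_planted)
    planted_pairs <- tibble::tibble(a = all_pairs[1, pick], b = all_pairs[2, pick])
  }

  # background edges over all gene pairs
  pair_idx <- utils::combn(seq_len(params$n_genes), 2)
  hit <- runif(ncol(pair_idx)) < params$bg_edge_prob
  bg <- data.frame(
    from = genes[pair_idx[1, hit]], to = genes[pair_idx[2, hit]],
    weight = runif(sum(hit), params$weight_range[1], params$weight_range[2])
  )

  draw_block <- function(a, b) {
    a_excl <- setdiff(members[[a]], members[[b]])
    b_excl <- setdiff(members[[b]], members[[a]])
    grid <- expand.grid(from = a_excl, to = b_excl, stringsAsFactors = FALSE)
    hit <- runif(nrow(grid)) < params$planted_edge_prob
    data.frame(
      from = grid$from[hit], to = grid$to[hit],
      weight = runif(
        sum(hit), params$planted_weight_range[1],
        params$planted_weight_range[2]
      )
    )
  }

  blocks <- purrr::map2(planted_pairs$a, planted_pairs$b, draw_block)
  build_network <- function() {
    fin_network(do.call(rbind, c(list(bg), blocks)))
  }
  net <- build_network()

  # guarantee the interactor filter for every planted orientation
  if (nrow(planted_pairs) > 0) {
    for (k in seq_len(nrow(planted_pairs))) {
      a <- planted_pairs$a[k]
      b <- planted_pairs$b[k]
      ok <- function(n) {
        restricted <- restrict_to_annotated(n, gs)
        length(neighbor_sets(restricted, gs, a, b)$n_ab) >= params$min_interactors &&
          length(neighbor_sets(restricted, gs, b, a)$n_ab) >= params$min_interactors
      }
      tries <- 0
      while (!ok(net)) {
        tries <- tries + 1
        if (tries > params$max_retries) {
          stop("could not satisfy min_interactors for planted pair ",
            a, " - ", b,
            call. = FALSE
          )
        }
        blocks[[k]] <- draw_block(a, b)
        net <- build_network()
      }
    }
  }

  planted_edges <- if (length(blocks) > 0) do.call(rbind, blocks) else NULL
  perturbed <- if (is.null(planted_edges)) {
    character(0)
  } else {
    unique(c(planted_edges$from, planted_edges$to))
  }
  pvals <- runif(params$n_genes)
  sel <- genes %in% perturbed
  pvals[sel] <- runif(sum(sel), 0, params$perturbed_p_max)
  pt <- perturbation(data.frame(gene = genes, pvalue = pvals))

  planted_links <- tibble::tibble(
    source = c(planted_pairs$a, planted_pairs$b),
    target = c(planted_pairs$b, planted_pairs$a)
  )
  planted_links <- planted_links[order(planted_links$source, planted_links$target), ]

  structure(
    list(
      network = net, gene_sets = gs, perturbation = pt,
      truth = structure(
        list(
          planted_links = planted_links, planted_pairs = planted_pairs,
          perturbed_genes = sort(perturbed), params = params, seed = seed
        ),
        class = "fixture_truth"
      )
    ),
    class = "cbpln_fixture"
  )
}

#' @export
print.cbpln_fixture <- function(x, ...) {
  cat("<cbpln_fixture> ", nrow(x$network), " edges, ",
    length(process_ids(x$gene_sets)), " processes, ",
    nrow(x$truth$planted_pairs), " planted links (seed ",
    x$truth$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Recovery metrics against fixture ground truth
#'
#' Power is the fraction of planted ordered pairs that were called; the false
#' positive fraction is the fraction of callable non-planted pairs that were
#' called.
#'
#' @param called Data frame of called ordered pairs (`source`, `target`).
#' @param truth A `fixture_truth` (or data frame of planted ordered pairs).
#' @param candidates Data frame of all evaluated ordered pairs; `called` must
#'   be a subset.
#' @return A one-row tibble: `power`, `false_positive_fraction`.
#' @export
evaluate_recovery <- function(called, truth, candidates) {
  planted <- if (inherits(truth, "fixture_truth")) truth$planted_links else truth
  key <- function(x) paste(x$source, x$target, sep = "\r")
  k_called <- unique(key(called))
  k_planted <- unique(key(planted))
  k_cand <- unique(key(candidates))
  if (!all(k_called %in% k_cand)) {
    stop("`called` must be a subset of `candidates`.", call. = FALSE)
  }
  if (length(k_planted) == 0L) {
    stop("no planted links in truth; power is undefined.", call. = FALSE)
  }
  n_nonplanted <- length(setdiff(k_cand, k_planted))
  fp <- length(setdiff(k_called, k_planted))
  tibble::tibble(
    power = length(intersect(k_called, k_planted)) / length(k_planted),
    false_positive_fraction = if (n_nonplanted == 0L) 0 else fp / n_nonplanted
  )
}

#' Write a fixture to disk as the three pipeline input files
#'
#' Writes `network.tsv` (raw weights, i.e. rescaled back by 1000 so the file
#' round-trips through [read_network()] defaults), `gene_sets.gmt`,
#' `perturbation.tsv` and `truth.tsv` (the planted ordered pairs).
#'
#' @param fixture A `cbpln_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(fixture$network, file.path(dir, "network.tsv"))
  write_gene_sets(fixture$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_perturbation(fixture$perturbation, file.path(dir, "perturbation.tsv"))
  utils::write.table(fixture$truth$planted_links, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
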