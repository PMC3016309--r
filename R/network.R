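#' Weighted functional interaction networks
#'
#' An undirected simple graph over genes with positive confidence weights,
#' stored as a tidy edge list (`from`, `to`, `weight`) with `from < to`
#' canonically. Self-loops are dropped and duplicate undirected pairs are
#' collapsed keeping the maximum weight (association dumps often list both
#' orientations; taking the maximum is conservative and order-independent).
#'
#' @param edges A data frame with columns `from`, `to`, `weight`.
#' @return A tibble of class `fin_network`.
#' @examples
#' net <- fin_network(data.frame(
#'   from = c("a", "b"), to = c("b", "c"), weight = c(0.8, 1)
#' ))
#' network_nodes(net)
#' @export
fin_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("from", "to", "weight") %in% names(edges))) {
    stop("`edges` must have columns `from`, `to`, `weight`.", call. = FALSE)
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- as.numeric(edges$weight)
  if (anyNA(from) || anyNA(to) || anyNA(weight)) {
    stop("missing values in edge list.", call. = FALSE)
  }
  if (any(weight <= 0)) stop("edge weights must be positive.", call. = FALSE)
  keep <- from != to
  from2 <- pmin(from[keep], to[keep])
  to2 <- pmax(from[keep], to[keep])
  tbl <- tibble::tibble(from = from2, to = to2, weight = weight[keep])
  tbl <- dplyr::arrange(tbl, .data$from, .data$to, dplyr::desc(.data$weight))
  tbl <- dplyr::distinct(tbl, .data$from, .data$to, .keep_all = TRUE)
  if (nrow(tbl) == 0L) stop("network has no edges.", call. = FALSE)
  structure(tbl, class = c("fin_network", class(tibble::tibble())))
}

#' @rdname fin_network
#' @param network A `fin_network`.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$from, network$to)))
}

#' @export
print.fin_network <- function(x, ...) {
  cat("<fin_network> ", nrow(x), " edges among ",
    length(network_nodes(x)), " genes\n",
    sep = ""
  )
  NextMethod()
}

#' Read a weighted interaction network from a 3-column edge list
#'
#' Expects tab-separated rows `gene1<TAB>gene2<TAB>weight` (no header; a
#' header row is tolerated and skipped when its third field is non-numeric).
#' Rows below `weight_min` are dropped before weights are divided by
#' `weight_scale`; with the defaults this maps STRING-style confidences
#' (150-1000, kept at >= 500) into (0, 1], so that a unit-weight edge carries
#' full confidence.
#'
#' @param path Path to the edge-list file.
#' @param weight_min Raw-weight threshold; rows strictly below it are dropped.
#' @param weight_scale Divisor applied to raw weights after thresholding.
#' @return A [fin_network].
#' @export
read_network <- function(path, weight_min = 500, weight_scale = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path,
    header = FALSE, colClasses = "character",
    stringsAsFactors = FALSE
  )
  if (ncol(raw) < 3L) stop("expected 3 tab-separated columns in ", path, call. = FALSE)
  w <- suppressWarnings(as.numeric(raw[[3L]]))
  if (is.na(w[1L]) && nrow(raw) > 1L) { # header row
    raw <- raw[-1L, , drop = FALSE]
    w <- suppressWarnings(as.numeric(raw[[3L]]))
  }
  if (anyNA(w)) {
    stop("non-numeric weight at row ", which(is.na(w))[1L], call. = FALSE)
  }
  keep <- w >= weight_min
  if (!any(keep)) {
    stop("no edges with weight >= ", weight_min, " in ", path, call. = FALSE)
  }
  fin_network(data.frame(
    from = raw[[1L]][keep], to = raw[[2L]][keep],
    weight = w[keep] / weight_scale
  ))
}

#' Write a network as a 3-column edge list
#'
#' Inverse of [read_network()]: weights are multiplied back by `weight_scale`
#' so a write/read round trip with matching parameters is lossless.
#'
#' @inheritParams read_network
#' @param network A [fin_network].
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, weight_scale = 1000) {
  out <- data.frame(
    from = network$from, to = network$to,
    weight = format(network$weight * weight_scale, digits = 17, scientific = FALSE, trim = TRUE)
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Restrict a network to annotated genes
#'
#' Keeps only edges whose two endpoints both lie in the annotation universe
#' (genes annotated by at least one process); isolated genes disappear with
#' their edges. Idempotent.
#'
#' @param network A [fin_network].
#' @param genesets A [gene_sets] collection.
#' @return The induced [fin_network] on the universe.
#' @export
restrict_to_annotated <- function(network, genesets) {
  u <- gene_universe(genesets)
  keep <- network$from %in% u & network$to %in% u
  if (!any(keep)) {
    stop("no network edges remain among annotated genes.", call. = FALSE)
  }
  fin_network(network[keep, , drop = FALSE])
}

#' Extract the interpretable subnetwork behind one link
#'
#' Returns the functional interactions that can contribute to the link from
#' `source` to `target`: edges with one endpoint in the source set and the
#' other in the target set. Interactions between genes within the same set are
#' excluded, so a gene annotated with both processes contributes no displayed
#' edges (any partner inside either set would make a within-set edge); it
#' still appears in the node table, labeled `"both"`.
#'
#' @param network A [fin_network].
#' @param genesets A [gene_sets] collection.
#' @param source,target Process identifiers.
#' @return A list of class `link_subnetwork` with tibbles `edges` (`from`,
#'   `to`, `weight`) and `nodes` (`gene`, `membership` in
#'   `source`/`target`/`both`).
#' @export
extract_link_subnetwork <- function(network, genesets, source, target) {
  ga <- set_members(genesets, source)
  gb <- set_members(genesets, target)
  in_a_from <- network$from %in% ga
  in_a_to <- network$to %in% ga
  in_b_from <- network$from %in% gb
  in_b_to <- network$to %in% gb
  cross <- (in_a_from & in_b_to) | (in_b_from & in_a_to)
  within <- (in_a_from & in_a_to) | (in_b_from & in_b_to)
  edges <- tibble::as_tibble(network[cross & !within, c("from", "to", "weight")])
  nodes_all <- network_nodes(network)
  genes <- nodes_all[nodes_all %in% union(ga, gb)]
  membership <- ifelse(genes %in% ga & genes %in% gb, "both",
    ifelse(genes %in% ga, "source", "target")
  )
  structure(
    list(
      edges = edges,
      nodes = tibble::tibble(gene = genes, membership = membership),
      source = source, target = target
    ),
    class = "link_subnetwork"
  )
}

#' @export
print.link_subnetwork <- function(x, ...) {
  cat("<link_subnetwork> ", x$source, " -> ", x$target, ": ",
    nrow(x$edges), " cross-set interactions, ", nrow(x$nodes), " genes\n",
    sep = ""
  )
  print(x$edges)
  invisible(x)
}

#' Write a link subnetwork in SIF format
#'
#' One line per interaction: `gene1<TAB>fi<TAB>gene2` ("fi" = functional
#' interaction), the plain-text format understood by Cytoscape.
#'
#' @param subnetwork A `link_subnetwork` from [extract_link_subnetwork()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(subnetwork, path) {
  lines <- character(0)
  if (nrow(subnetwork$edges) > 0L) {
    lines <- paste(subnetwork$edges$from, "fi", subnetwork$edges$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
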