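#' Gene set collections
#'
#' A gene set collection holds the biological processes under study and their
#' gene memberships, in long (tidy) form: one row per (set, gene) pair. The
#' *universe* is the set of all genes annotated by at least one process; it is
#' the sampling frame for every randomization and enrichment computation in the
#' package. Gene identifiers are opaque, case-sensitive strings; no identifier
#' mapping is performed — the three inputs (sets, network, perturbation table)
#' must already share a namespace.
#'
#' @param x A data frame with columns `set` and `gene`, or a named list of
#'   character vectors (one element per process).
#' @param descriptions Optional named character vector of free-text process
#'   descriptions; names must be process identifiers.
#' @return A tibble of class `gene_sets` with columns `set` and `gene`,
#'   duplicates removed, carrying the descriptions as an attribute.
#' @examples
#' gs <- gene_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' gene_universe(gs)
#' @export
gene_sets <- function(x, descriptions = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("set", "gene") %in% names(x))) {
      stop("`x` must have columns `set` and `gene`.", call. = FALSE)
    }
    tbl <- tibble::tibble(set = as.character(x$set), gene = as.character(x$gene))
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("list input must be fully named by process identifier.", call. = FALSE)
    }
    tbl <- tibble::tibble(
      set = rep(names(x), lengths(x)),
      gene = as.character(unlist(x, use.names = FALSE))
    )
  } else {
    stop("`x` must be a data frame or a named list.", call. = FALSE)
  }
  if (nrow(tbl) == 0L) stop("gene set collection is empty.", call. = FALSE)
  if (anyNA(tbl$set) || anyNA(tbl$gene) || any(tbl$gene == "")) {
    stop("missing or empty gene/set identifiers.", call. = FALSE)
  }
  tbl <- dplyr::distinct(tbl)
  empty <- setdiff(unique(tbl$set), tbl$set[tbl$gene != ""])
  if (length(empty) > 0L) {
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!is.null(descriptions)) {
    descriptions <- descriptions[intersect(names(descriptions), unique(tbl$set))]
  }
  structure(
    tbl,
    descriptions = descriptions,
    class = c("gene_sets", class(tibble::tibble()))
  )
}

#' @rdname gene_sets
#' @param genesets A `gene_sets` collection.
#' @export
gene_universe <- function(genesets) {
  sort(unique(genesets$gene))
}

#' @rdname gene_sets
#' @export
process_ids <- function(genesets) {
  sort(unique(genesets$set))
}

# named list of member vectors, sorted for deterministic iteration
set_list <- function(genesets) {
  lapply(split(genesets$gene, genesets$set), unique)
}

set_members <- function(genesets, process) {
  members <- unique(genesets$gene[genesets$set == process])
  if (length(members) == 0L) {
    stop("unknown process: ", process, call. = FALSE)
  }
  members
}

#' @export
print.gene_sets <- function(x, ...) {
  sets <- unique(x$set)
  cat("<gene_sets> ", length(sets), " sets, ",
    length(unique(x$gene)), " genes in universe\n",
    sep = ""
  )
  NextMethod()
}

#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT format used by MSigDB and friends: one set per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A [gene_sets] collection.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no gene sets in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields.",
      call. = FALSE
    )
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate set name(s): ",
      paste(unique(names_[duplicated(names_)]), collapse = ", "),
      call. = FALSE
    )
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(lengths(members) == 0L)
  if (length(empty) > 0L) {
    stop("empty gene set at line ", empty[1L], ": ", names_[empty[1L]],
      call. = FALSE
    )
  }
  gene_sets(stats::setNames(members, names_),
    descriptions = stats::setNames(descs, names_)
  )
}

#' Write gene sets to a GMT file
#'
#' @param genesets A [gene_sets] collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(genesets, path) {
  sl <- set_list(genesets)
  descs <- attr(genesets, "descriptions")
  lines <- vapply(names(sl), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, sl[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
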