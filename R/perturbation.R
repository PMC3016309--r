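#' Per-gene perturbation tables
#'
#' Differential-expression p-values (e.g. from a limma contrast of two
#' conditions) and the derived perturbation score
#' `s(g) = |log(pvalue, base)|`. A p-value of 1 gives score 0; zero p-values
#' are floored at `pvalue_floor` before taking the logarithm. Genes absent
#' from the table score 0 when queried: absence of evidence contributes
#' nothing to a link.
#'
#' @param x A data frame with columns `gene` and `pvalue`.
#' @param log_base Base of the logarithm used for the score (default 10).
#' @param pvalue_floor Replacement for p-values equal to 0.
#' @return A tibble of class `perturbation` with columns `gene`, `pvalue`,
#'   `score`.
#' @examples
#' pt <- perturbation(data.frame(gene = c("g1", "g2"), pvalue = c(0.01, 1)))
#' perturbation_scores(pt, c("g1", "g2", "absent"))
#' @export
perturbation <- function(x, log_base = 10, pvalue_floor = 1e-300) {
  if (!is.data.frame(x) || !all(c("gene", "pvalue") %in% names(x))) {
    stop("`x` must have columns `gene` and `pvalue`.", call. = FALSE)
  }
  if (log_base <= 1) stop("`log_base` must be > 1.", call. = FALSE)
  gene <- as.character(x$gene)
  p <- as.numeric(x$pvalue)
  if (anyNA(p)) {
    stop("non-numeric p-value for gene ", gene[which(is.na(p))[1L]], call. = FALSE)
  }
  bad <- p < 0 | p > 1
  if (any(bad)) {
    stop("p-value outside [0, 1] for gene ", gene[which(bad)[1L]], call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene(s) in perturbation table: ",
      paste(unique(gene[duplicated(gene)])[1:3], collapse = ", "),
      call. = FALSE
    )
  }
  p_eff <- pmax(p, pvalue_floor)
  structure(
    tibble::tibble(gene = gene, pvalue = p, score = abs(log(p_eff, base = log_base))),
    log_base = log_base, pvalue_floor = pvalue_floor,
    class = c("perturbation", class(tibble::tibble()))
  )
}

#' @rdname perturbation
#' @param perturbation A `perturbation` table.
#' @param genes Character vector of gene identifiers.
#' @export
perturbation_scores <- function(perturbation, genes) {
  idx <- match(genes, perturbation$gene)
  out <- perturbation$score[idx]
  out[is.na(idx)] <- 0
  out
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> ", nrow(x), " genes (log base ",
    attr(x, "log_base"), ")\n",
    sep = ""
  )
  NextMethod()
}

#' Read a per-gene p-value table
#'
#' Expects tab-separated rows `gene<TAB>pvalue` (a header row is tolerated
#' when its second field is non-numeric).
#'
#' @param path Path to the table.
#' @inheritParams perturbation
#' @return A [perturbation] table.
#' @export
read_perturbation <- function(path, log_base = 10, pvalue_floor = 1e-300) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path,
    header = FALSE, colClasses = "character",
    stringsAsFactors = FALSE
  )
  if (ncol(raw) < 2L) stop("expected 2 tab-separated columns in ", path, call. = FALSE)
  p <- suppressWarnings(as.numeric(raw[[2L]]))
  if (is.na(p[1L]) && nrow(raw) > 1L) { # header row
    raw <- raw[-1L, , drop = FALSE]
    p <- suppressWarnings(as.numeric(raw[[2L]]))
  }
  perturbation(data.frame(gene = raw[[1L]], pvalue = p),
    log_base = log_base, pvalue_floor = pvalue_floor
  )
}

#' Write a per-gene p-value table
#'
#' @param perturbation A [perturbation] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perturbation <- function(perturbation, path) {
  out <- data.frame(
    gene = perturbation$gene,
    pvalue = format(perturbation$pvalue, digits = 17, trim = TRUE)
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
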