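link_columns <- c(
  "source", "target", "n_neighbors", "n_linked", "score", "background",
  "normalized", "p_geneset", "p_network", "q_geneset", "q_network", "bpln_p"
)

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

serialize_contributions <- function(tbl) {
  if (is.null(tbl) || nrow(tbl) == 0L) {
    return("")
  }
  paste(
    sprintf(
      "%s=%s|%s|%s", tbl$gene,
      fmt_num(tbl$score), fmt_num(tbl$f_source), fmt_num(tbl$product)
    ),
    collapse = ";"
  )
}

deserialize_contributions <- function(s) {
  if (is.na(s) || s == "") {
    return(tibble::tibble(
      gene = character(), score = numeric(),
      f_source = numeric(), product = numeric()
    ))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "[=|]")
  tibble::tibble(
    gene = vapply(parts, `[[`, character(1), 1L),
    score = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    f_source = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    product = as.numeric(vapply(parts, `[[`, character(1), 4L))
  )
}

#' Write link records to a tab-separated file
#'
#' One row per evaluated ordered process pair, sorted by (source, target).
#' Numeric fields are written with 17 significant digits and the per-gene
#' contribution table is packed into one column
#' (`gene=score|f_source|product;...`), so [read_links()] round-trips the
#' records losslessly.
#'
#' @param links Tibble of link records ([compute_cbpln()]`$links`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  cols <- intersect(link_columns, names(links))
  out <- links[order(links$source, links$target), , drop = FALSE]
  flat <- data.frame(
    source = out$source, target = out$target,
    stringsAsFactors = FALSE
  )
  for (col in setdiff(cols, c("source", "target"))) {
    flat[[col]] <- if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      fmt_num(out[[col]])
    } else {
      out[[col]]
    }
  }
  flat$contributions <- if ("contributions" %in% names(out)) {
    vapply(out$contributions, serialize_contributions, character(1))
  } else {
    ""
  }
  utils::write.table(flat, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read link records written by [write_links()]
#'
#' @param path Path to the file.
#' @return A tibble of link records with a `contributions` list-column.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path,
    header = TRUE, colClasses = "character",
    stringsAsFactors = FALSE
  )
  out <- tibble::as_tibble(raw)
  for (col in intersect(
    c(
      "score", "background", "normalized", "p_geneset", "p_network",
      "q_geneset", "q_network", "bpln_p"
    ),
    names(out)
  )) {
    out[[col]] <- as.numeric(out[[col]])
  }
  for (col in intersect(c("n_neighbors", "n_linked"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  if ("contributions" %in% names(out)) {
    out$contributions <- lapply(out$contributions, deserialize_contributions)
  }
  out
}
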