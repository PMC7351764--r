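#' Upper-tail hypergeometric p-value for over-representation
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` term members in a hit list of size `n` sampled without
#' replacement from a universe of `N` genes of which `K` carry the term.
#' Evaluated through the stable log-space tail routine of
#' [stats::phyper()].
#'
#' @param k observed hits in the term.
#' @param K term size within the universe.
#' @param n hit-list size.
#' @param N universe size.
#' @return the upper-tail p-value.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0) ||
      any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("hypergeometric parameters violate 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation test
#'
#' Flat hypergeometric over-representation over a supplied term -> gene
#' annotation (the term structure is taken at face value; no ontology
#' graph decorrelation). The effective universe for each term is the
#' supplied universe; annotated genes outside the universe are ignored.
#' P-values are Benjamini-Hochberg adjusted across the tested terms.
#'
#' @param hits character vector of hit gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector, the assayed gene universe.
#' @param ann named list term_id -> character vector of gene ids, or a
#'   two-column data.frame (term_id, gene_id).
#' @param labels optional named character vector term_id -> label.
#' @return data.frame sorted by p-value: `term_id`, `label`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adj_p`; one row per term intersecting the
#'   universe.
#' @export
enrich <- function(hits, universe, ann, labels = NULL) {
  hits <- unique(hits); universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray))
    stop("hits outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ...")
  if (is.data.frame(ann)) {
    ann <- split(as.character(ann[[2]]), as.character(ann[[1]]))
  }
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(ann), function(tid) {
    gs <- intersect(unique(ann[[tid]]), universe)
    if (!length(gs)) return(NULL)
    k <- length(intersect(hits, gs))
    data.frame(term_id = tid,
               label = if (!is.null(labels) && tid %in% names(labels))
                 labels[[tid]] else NA_character_,
               k = k, K = length(gs), n = n, N = N,
               p_value = hypergeom_upper(k, length(gs), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), label = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), adj_p = numeric(),
                      stringsAsFactors = FALSE))
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Read a term -> gene annotation from TSV or GMT
#'
#' @param path two-column TSV (term_id, gene_id; with or without header)
#'   or a GMT file (term, description, genes...).
#' @param format `"tsv"` or `"gmt"`.
#' @return named list term_id -> gene ids; GMT descriptions are attached
#'   as attribute `"labels"`.
#' @export
read_annotation <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ann <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                           vapply(parts, `[`, character(1), 1))
    attr(ann, "labels") <- stats::setNames(
      vapply(parts, `[`, character(1), 2), names(ann))
    return(ann)
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "term_id")) df <- df[-1, , drop = FALSE]
  split(as.character(df[[2]]), as.character(df[[1]]))
}
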