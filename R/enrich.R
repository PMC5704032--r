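#' Right-tail hypergeometric probability
#'
#' Probability of drawing `k` or more members of a `K`-gene set when `n`
#' genes are drawn without replacement from a universe of `N`:
#' `p = sum_{j = k..min(K, n)} C(K, j) C(N-K, n-j) / C(N, n)`, evaluated
#' through the stable log-space hypergeometric tail.  Vectorized over `k`.
#'
#' @param N universe size.
#' @param K set size.
#' @param n query size.
#' @param k overlap count.
#' @return p-value in (0, 1].
#' @export
hyper_right_tail <- function(N, K, n, k) {
  if (K > N || n > N || any(k > pmin(K, n)) || any(k < 0))
    stop("impossible hypergeometric configuration")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests each set of the collection for over-representation of the query
#' genes with the right-tail hypergeometric test against the universe
#' (default: the union of all set members).  Query genes outside the
#' universe are dropped (count recorded in the `"n_dropped"` attribute);
#' an empty effective query yields an empty result with a warning rather
#' than an error.
#'
#' @param query character vector of gene ids.
#' @param collection named list of gene sets.
#' @param universe optional background gene vector overriding the
#'   collection union.
#' @return data.frame with one row per set: `set`, `K` (set size), `n`
#'   (effective query size), `k` (overlap), `p_value`, `q_value`
#'   (Benjamini-Hochberg over all sets), `overlap` (`;`-collapsed genes);
#'   ordered by ascending p then canonical set name.
#' @export
enrich <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- gene_set_universe(collection)
  universe <- unique(universe)
  q <- unique(query)
  eff <- intersect(q, universe)
  n_dropped <- length(q) - length(eff)
  if (!length(eff)) {
    warning("no query genes in the universe; empty enrichment result")
    out <- data.frame(set = character(0), K = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  N <- length(universe); n <- length(eff)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    ov <- intersect(eff, members)
    data.frame(set = nm, K = length(members), n = n, k = length(ov),
               p_value = hyper_right_tail(N, length(members), n, length(ov)),
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, canonical_pathway_name(out$set)), ,
             drop = FALSE]
  out <- out[c("set", "K", "n", "k", "p_value", "q_value", "overlap")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Top-k ranked pathway names
#'
#' Orders enrichment rows by ascending p-value, breaking ties by the
#' canonicalized (lower-case) set name so rankings are stable across runs,
#' and returns the first `k` names.
#'
#' @param rows output of [enrich()].
#' @param k list length (default 20).
#' @return character vector of at most `k` set names, in rank order.
#' @export
top_pathways <- function(rows, k = 20) {
  ord <- order(rows$p_value, canonical_pathway_name(rows$set))
  rows$set[ord][seq_len(min(k, nrow(rows)))]
}

#' Canonical pathway name
#'
#' Lower-cases, trims and collapses whitespace so that punctuation/case
#' variants of one pathway name compare equal in profile set operations.
#'
#' @param x character vector of names.
#' @return canonicalized names.
#' @export
canonical_pathway_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}
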