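#' Hypergeometric term over-representation
#'
#' One-sided hypergeometric test per annotation term: the p-value is the
#' probability of observing at least the seen overlap between the query and
#' the term's gene set when drawing `|query|` genes from the universe.
#' Benjamini-Hochberg step-up is applied across exactly the terms with
#' nonzero query overlap.
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param annotation named list mapping term id to a character vector of
#'   member genes (members outside the universe are ignored).
#' @param universe character vector of all assayable gene ids.
#' @param alpha adjusted-p cutoff used when `filter = TRUE`.
#' @param descriptions optional named character vector of term descriptions.
#' @param filter keep only terms with `adjusted_p <= alpha`?
#' @return data frame with columns `term`, `description`, `overlap`,
#'   `term_size`, `p_value`, `adjusted_p`, `cluster_frequency` (overlap as
#'   a fraction of the query), sorted by increasing p-value.
#' @examples
#' universe <- paste0("g", 1:10)
#' term_enrichment(c("g1", "g2", "g3"),
#'                 list(T1 = paste0("g", 1:5)), universe, filter = FALSE)
#' @export
term_enrichment <- function(query, annotation, universe, alpha = 0.05,
                            descriptions = NULL, filter = TRUE) {
  abort_if(length(query) == 0, "`query` is empty")
  abort_if(length(universe) == 0, "`universe` is empty")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  abort_if(!all(query %in% universe), "`query` must be a subset of `universe`")
  annotation <- lapply(annotation, function(gs) {
    intersect(unique(as.character(gs)), universe)
  })
  overlap <- vapply(annotation, function(gs) {
    length(intersect(query, gs))
  }, integer(1))
  tested <- names(annotation)[overlap > 0]
  N <- length(universe); n <- length(query)
  rows <- lapply(tested, function(term) {
    K <- length(annotation[[term]])
    k <- overlap[[term]]
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               description = if (!is.null(descriptions) &&
                                 term %in% names(descriptions))
                 unname(descriptions[term]) else term,
               overlap = k, term_size = K, p_value = p,
               cluster_frequency = k / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), description = character(0),
                      overlap = integer(0), term_size = integer(0),
                      p_value = numeric(0), cluster_frequency = numeric(0))
  }
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  if (filter) out <- out[out$adjusted_p <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "description", "overlap", "term_size", "p_value",
          "adjusted_p", "cluster_frequency")]
}

#' Gene-set similarity
#'
#' Jaccard coefficient `|A n B| / |A u B|` or overlap coefficient
#' `|A n B| / min(|A|, |B|)`.
#'
#' @param a,b character vectors of gene ids.
#' @param similarity `"jaccard"` or `"overlap"`.
#' @return a number in `[0, 1]`.
#' @export
set_similarity <- function(a, b, similarity = c("jaccard", "overlap")) {
  similarity <- match.arg(similarity)
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  if (inter == 0) return(0)
  if (similarity == "jaccard") inter / length(union(a, b))
  else inter / min(length(a), length(b))
}

#' Enrichment-map graph
#'
#' Builds the similarity graph over named gene sets used to visualize
#' enrichment results: nodes carry set size and p-value, edge weights are
#' Jaccard or overlap coefficients, and edges below `cutoff` are omitted.
#'
#' @param sets named list of character vectors (gene sets).
#' @param p_values optional named numeric vector of per-set p-values.
#' @param similarity `"jaccard"` or `"overlap"`.
#' @param cutoff minimum edge weight retained.
#' @return list with data frames `nodes` (`set`, `size`, `p_value`) and
#'   `edges` (`from`, `to`, `weight`).
#' @export
enrichment_map <- function(sets, p_values = NULL,
                           similarity = c("jaccard", "overlap"),
                           cutoff = 0.25) {
  similarity <- match.arg(similarity)
  abort_if(length(sets) == 0 || any(lengths(sets) == 0),
           "every gene set must be nonempty")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  nodes <- data.frame(
    set = names(sets),
    size = lengths(lapply(sets, unique)),
    p_value = if (is.null(p_values)) NA_real_
              else unname(p_values[names(sets)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  from <- character(0); to <- character(0); weight <- numeric(0)
  nm <- names(sets)
  if (length(sets) > 1) {
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        w <- set_similarity(sets[[i]], sets[[j]], similarity)
        if (w >= cutoff && w > 0) {
          from <- c(from, nm[i]); to <- c(to, nm[j]); weight <- c(weight, w)
        }
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, weight = weight,
                          stringsAsFactors = FALSE))
}
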