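# Generic over-representation analysis (ORA): hypergeometric upper-tail
# test of a query gene list against annotation sets, with Benjamini-
# Hochberg correction. Source-agnostic — sets come from any GMT file.

#' Over-representation analysis
#'
#' For each set, tests whether the query hits it more often than expected
#' under hypergeometric sampling from the universe:
#' `p = P[X >= k]`, `X ~ Hypergeometric(N, K, n)` with `N` the universe
#' size, `K` the set size within the universe, `n` the query size and `k`
#' the observed overlap. Query members outside the universe are dropped
#' with a warning; each set is intersected with the universe. Results are
#' sorted by p then `set_id`; q-values are Benjamini-Hochberg over the
#' tested sets.
#'
#' @param query Character vector of gene/accession identifiers.
#' @param sets Gene-set tibble ([read_gene_sets()]).
#' @param universe Character vector; the background. The standard choice is
#'   every precursor accession in the quant table.
#' @param min_size,max_size Set-size bounds (after universe intersection);
#'   sets outside are skipped.
#' @return A tibble `set_id`, `description`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment` (`(k/n)/(K/N)`), `p_value`, `q_value`.
#' @export
ora <- function(query, sets, universe, min_size = 3, max_size = 500) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query member(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  if (n == 0L) stop("empty query after universe filtering", call. = FALSE)
  rows <- purrr::pmap_dfr(
    list(sets$set_id, sets$description, sets$members),
    function(set_id, description, members) {
      in_universe <- intersect(members, universe)
      K <- length(in_universe)
      if (K < min_size || K > max_size) return(NULL)
      k <- length(intersect(query, in_universe))
      # upper tail P[X >= k] = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      tibble::tibble(
        set_id = set_id, description = description,
        k = k, K = K, n = n, N = N,
        fold_enrichment = (k / n) / (K / N),
        p_value = p
      )
    }
  )
  if (nrow(rows) == 0L) {
    return(tibble::tibble(set_id = character(0), description = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), fold_enrichment = numeric(0),
                          p_value = numeric(0), q_value = numeric(0)))
  }
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  dplyr::arrange(rows, .data$p_value, .data$set_id)
}
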