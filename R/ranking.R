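# Candidate-peptide selection: assemble the per-precursor decision table
# (differential statistics + physicochemical panel) and rank candidates by
# a transparent weighted rank-sum. The score operationalizes the qualitative
# selection rationale — stronger differential expression, longer half-life,
# more hydrophobic, predicted stable — and is reported alongside, never
# instead of, the raw criterion table.

#' Build the candidate decision table for one precursor
#'
#' Candidates are all significant peptides of the given precursor (by
#' default the precursor with the most significant peptides). Differential
#' statistics are joined with the physicochemical panel, one row per
#' distinct candidate sequence.
#'
#' @param diff A [test_peptides()] result.
#' @param profiles A [physchem_profile()] result covering the candidate
#'   sequences.
#' @param precursor_acc Accession; default = the top-ranked precursor by
#'   significant-peptide count.
#' @return A tibble `peptide_id`, `sequence`, `precursor_acc`, `log2fc`,
#'   `p_value`, `half_life_h`, `gravy`, `aliphatic_index`,
#'   `instability_index`, `stable`.
#' @export
build_candidate_table <- function(diff, profiles, precursor_acc = NULL) {
  stopifnot(inherits(diff, "pep_diff"))
  if (is.null(precursor_acc)) {
    tp <- top_precursors(diff, diff)
    if (nrow(tp) == 0L) stop("no significant peptides in any precursor",
                             call. = FALSE)
    precursor_acc <- tp$precursor_acc[1]
  }
  cand <- diff |>
    dplyr::filter(.data$precursor_acc == !!precursor_acc, .data$significant) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE)
  if (nrow(cand) == 0L) {
    stop("precursor ", precursor_acc, " has no significant peptides",
         call. = FALSE)
  }
  prof <- dplyr::distinct(tibble::as_tibble(profiles), .data$sequence,
                          .keep_all = TRUE)
  cand |>
    dplyr::select("peptide_id", "sequence", "precursor_acc", "log2fc",
                  "p_value") |>
    dplyr::left_join(
      dplyr::select(prof, "sequence", "half_life_h", "gravy",
                    "aliphatic_index", "instability_index", "stable"),
      by = "sequence"
    ) |>
    dplyr::arrange(.data$sequence)
}

#' Rank candidate peptides by weighted rank-sum
#'
#' Each criterion is converted to a within-table rank (1 = best): smaller
#' p-value, larger |log2 fold change|, longer half-life, larger GRAVY
#' (more hydrophobic), and stable before unstable. Ranks are combined as a
#' weighted sum (`rank_score`; smaller is better) and the final order
#' breaks ties alphabetically by sequence. Because only ranks enter, the
#' score is invariant to monotone rescaling of any single criterion.
#'
#' @param table A [build_candidate_table()] result.
#' @param weights Named numeric weights for `p`, `fc`, `half_life`,
#'   `gravy`, `stable`; default equal.
#' @return The table with `rank_p`, `rank_fc`, `rank_half_life`,
#'   `rank_gravy`, `rank_stable`, `rank_score` and `rank` columns, sorted
#'   by rank.
#' @export
rank_candidates <- function(table,
                            weights = c(p = 1, fc = 1, half_life = 1,
                                        gravy = 1, stable = 1)) {
  needed <- c("p", "fc", "half_life", "gravy", "stable")
  stopifnot(all(needed %in% names(weights)))
  r <- function(x) rank(x, ties.method = "average")
  out <- table |>
    dplyr::mutate(
      rank_p = r(.data$p_value),
      rank_fc = r(-abs(.data$log2fc)),
      rank_half_life = r(-.data$half_life_h),
      rank_gravy = r(-.data$gravy),
      rank_stable = r(-as.numeric(.data$stable)),
      rank_score = weights[["p"]] * .data$rank_p +
        weights[["fc"]] * .data$rank_fc +
        weights[["half_life"]] * .data$rank_half_life +
        weights[["gravy"]] * .data$rank_gravy +
        weights[["stable"]] * .data$rank_stable
    ) |>
    dplyr::arrange(.data$rank_score, .data$sequence) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}
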