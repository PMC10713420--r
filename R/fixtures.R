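# Packaged reference fixtures: the printed differential-peptide table (40
# rows), the domain-containment table (34 rows), the seven candidate
# peptides with their printed descriptor values, and a synthetic scaffold
# standing in for the Actg2 precursor.

fixture_path <- function(file) {
  system.file("extdata", file, package = "pepdiff", mustWork = TRUE)
}

#' Top differentially expressed peptides fixture (40 rows)
#'
#' The 20 most up- and 20 most down-regulated peptides as printed, with
#' accession, gene symbol, sequence, integer labeled mass, fold change and
#' p-value. Note the printed mass column is in Da. The table prints
#' `VFPSIVGR` where the candidate list uses `VFPSIVGRP`; both are stored
#' verbatim, per source (see [pep_candidates()]'s `table1_sequence`
#' column), rather than silently reconciled.
#'
#' @return A 40-row tibble.
#' @export
pep_table1 <- function() {
  readr::read_tsv(fixture_path("table1_deps.tsv"), show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(gene = readr::col_character())) |>
    dplyr::mutate(gene = dplyr::coalesce(.data$gene, ""))
}

#' Domain-located peptides fixture (34 rows)
#'
#' Peptides located within annotated functional domains of their
#' precursors: peptide coordinates and domain intervals, 1-based inclusive.
#'
#' @return A 34-row tibble with `sequence`, `gene`, `start`, `end`,
#'   `domain_start`, `domain_end`, `domain_name`, `direction`.
#' @export
pep_table2 <- function() {
  readr::read_tsv(fixture_path("table2_domains.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Candidate peptide fixture (7 Actg2-derived peptides)
#'
#' The seven Actg2-derived candidate peptides with their printed aliphatic
#' index, GRAVY and half-life values, plus fold change and p-value from the
#' differential table (`table1_sequence` records the sequence as printed
#' there, which differs for Actg2-3).
#'
#' @return A 7-row tibble.
#' @export
pep_candidates <- function() {
  readr::read_tsv(fixture_path("candidates.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Synthetic Actg2 precursor scaffold
#'
#' A 380-residue synthetic sequence that embeds the seven candidate
#' peptides at their printed precursor coordinates (each occurring exactly
#' once, also under I/L equivalence), with the 3-376 Actin domain interval
#' attached. It is a coordinate-faithful stand-in for the rat Actg2
#' precursor built for offline location tests; it is **not** the real
#' UniProt P63269 sequence.
#'
#' @return A list: `precursors` (1-row precursor tibble, accession
#'   `P63269-SYNTHETIC`) and `domains` (1-row domain tibble).
#' @export
pep_actg2_scaffold <- function() {
  prec <- read_precursor_fasta(fixture_path("p63269_synthetic.fasta"))
  domains <- tibble::tibble(
    accession = prec$accession, start = 3L, end = 376L,
    name = "Actin", description = "actin family domain", attached = TRUE
  )
  list(precursors = prec, domains = domains)
}
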