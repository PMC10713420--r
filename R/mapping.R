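# Peptide-to-precursor mapping: exact substring location (with an I/L
# equivalence fallback, since MS cannot distinguish Ile from Leu),
# cleavage-site context in protease nomenclature (P1 | P1' across the cut
# bond), domain containment, per-residue coverage and cleavage-residue
# frequency profiling.

NTERM_SENTINEL <- "PROT-NTERM"
CTERM_SENTINEL <- "PROT-CTERM"

locate_one <- function(sequence, prec_seq) {
  hits <- stringr::str_locate_all(prec_seq, stringr::fixed(sequence))[[1]]
  mode <- "exact"
  if (nrow(hits) == 0L) {
    hits <- stringr::str_locate_all(chartr("I", "L", prec_seq),
                                    stringr::fixed(chartr("I", "L", sequence)))[[1]]
    mode <- "IL-equivalent"
  }
  if (nrow(hits) == 0L) return(NULL)
  list(starts = hits[, 1], mode = mode)
}

#' Locate peptides in their precursor proteins
#'
#' Finds every exact occurrence of each peptide in its precursor; when none
#' exists, retries with I/L treated as equivalent (flagged as match mode
#' `IL-equivalent`). Multi-hit peptides use the first occurrence for
#' coordinates, with all start positions recorded. Cleavage context is
#' attached: for the N-terminal cut, P1 is the precursor residue before the
#' peptide (sentinel `PROT-NTERM` at position 1) and P1' the first peptide
#' residue; for the C-terminal cut, P1 is the last peptide residue and P1'
#' the precursor residue after it (sentinel `PROT-CTERM` at the end).
#'
#' @param peptides Data frame with `sequence` and `precursor_acc` columns
#'   (optional `peptide_id`).
#' @param precursors Precursor tibble ([read_precursor_fasta()]).
#' @return A tibble, one row per peptide: `peptide_id`, `sequence`,
#'   `precursor_acc`, `hit` (logical), `start`, `end` (1-based inclusive),
#'   `match_mode`, `multi_hit`, `n_hits`, `all_starts` (list-column),
#'   `nterm_p1`, `nterm_p1p`, `cterm_p1`, `cterm_p1p`. Peptides whose
#'   precursor is absent or not matched have `hit = FALSE` and NA
#'   coordinates.
#' @export
locate_peptides <- function(peptides, precursors) {
  peptides <- tibble::as_tibble(peptides)
  stopifnot(all(c("sequence", "precursor_acc") %in% names(peptides)))
  ids <- if ("peptide_id" %in% names(peptides)) {
    as.character(peptides$peptide_id)
  } else {
    peptides$sequence
  }
  prec <- stats::setNames(precursors$sequence, precursors$accession)
  rows <- purrr::pmap(
    list(ids, peptides$sequence, peptides$precursor_acc),
    function(id, seq_, acc) {
      base <- tibble::tibble(
        peptide_id = id, sequence = seq_, precursor_acc = acc,
        hit = FALSE, start = NA_integer_, end = NA_integer_,
        match_mode = NA_character_, multi_hit = NA, n_hits = 0L,
        all_starts = list(integer(0)),
        nterm_p1 = NA_character_, nterm_p1p = NA_character_,
        cterm_p1 = NA_character_, cterm_p1p = NA_character_
      )
      if (!acc %in% names(prec)) return(base)
      loc <- locate_one(seq_, prec[[acc]])
      if (is.null(loc)) return(base)
      start <- as.integer(loc$starts[1])
      end <- start + nchar(seq_) - 1L
      ctx <- cleavage_context(start, end, prec[[acc]])
      tibble::tibble(
        peptide_id = id, sequence = seq_, precursor_acc = acc,
        hit = TRUE, start = start, end = end,
        match_mode = loc$mode, multi_hit = length(loc$starts) > 1L,
        n_hits = length(loc$starts),
        all_starts = list(as.integer(loc$starts)),
        nterm_p1 = ctx$nterm_p1, nterm_p1p = ctx$nterm_p1p,
        cterm_p1 = ctx$cterm_p1, cterm_p1p = ctx$cterm_p1p
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Cleavage-site context for a mapped interval
#'
#' @param start,end 1-based inclusive peptide coordinates in the precursor.
#' @param prec_seq Precursor sequence string.
#' @return A list `nterm_p1`, `nterm_p1p`, `cterm_p1`, `cterm_p1p`;
#'   sentinels `PROT-NTERM`/`PROT-CTERM` mark peptides flush with a protein
#'   terminus (no cut bond there).
#' @export
cleavage_context <- function(start, end, prec_seq) {
  n <- nchar(prec_seq)
  stopifnot(start >= 1, end <= n, start <= end)
  list(
    nterm_p1 = if (start == 1L) NTERM_SENTINEL else
      substr(prec_seq, start - 1L, start - 1L),
    nterm_p1p = substr(prec_seq, start, start),
    cterm_p1 = substr(prec_seq, end, end),
    cterm_p1p = if (end == n) CTERM_SENTINEL else
      substr(prec_seq, end + 1L, end + 1L)
  )
}

#' Domain containment and overlap for mapped peptides
#'
#' A peptide is *contained* in a domain when
#' `domain.start <= start && end <= domain.end`; it *overlaps* when the
#' intervals intersect at all. Containment implies overlap.
#'
#' @param mappings A [locate_peptides()] result.
#' @param domains A domain tibble ([read_domain_table()]).
#' @return `mappings` with list-columns `domains_containing` and
#'   `domains_overlapping` (domain names) plus `in_domain` (logical).
#' @export
annotate_domains <- function(mappings, domains) {
  doms <- split(domains, domains$accession)
  res <- purrr::pmap(
    list(mappings$precursor_acc, mappings$start, mappings$end),
    function(acc, start, end) {
      if (is.na(start) || is.null(doms[[acc]])) {
        return(list(containing = character(0), overlapping = character(0)))
      }
      d <- doms[[acc]]
      overlapping <- d$name[d$start <= end & start <= d$end]
      containing <- d$name[d$start <= start & end <= d$end]
      list(containing = containing, overlapping = overlapping)
    }
  )
  mappings$domains_containing <- purrr::map(res, "containing")
  mappings$domains_overlapping <- purrr::map(res, "overlapping")
  mappings$in_domain <- lengths(mappings$domains_containing) > 0L
  mappings
}

#' Per-residue peptide coverage of a precursor
#'
#' The "peptide alignment map": for each precursor residue, how many mapped
#' peptides cover it — overall and split by differential direction when a
#' [test_peptides()] result is supplied. The total coverage sums to the
#' summed length of the mapped peptides (conservation).
#'
#' @param mappings [locate_peptides()] result (rows for one or more
#'   precursors; non-hits ignored).
#' @param precursor One row of a precursor tibble, or an accession present
#'   in `mappings`.
#' @param diff Optional `pep_diff` result used to split peptides into
#'   up/down.
#' @return A tibble `precursor_acc`, `position`, `residue`, `n_all`,
#'   `n_up`, `n_down`.
#' @export
coverage_map <- function(mappings, precursor, diff = NULL) {
  if (is.character(precursor)) {
    acc <- precursor
    prec_seq <- NULL
  } else {
    acc <- precursor$accession[1]
    prec_seq <- precursor$sequence[1]
  }
  hits <- dplyr::filter(mappings, .data$precursor_acc == acc, .data$hit)
  n <- if (!is.null(prec_seq)) nchar(prec_seq) else max(hits$end, 0L)
  cover <- function(rows) {
    v <- integer(n)
    for (i in seq_len(nrow(rows))) {
      idx <- rows$start[i]:rows$end[i]
      v[idx] <- v[idx] + 1L
    }
    v
  }
  dir_of <- function(ids) {
    if (is.null(diff)) return(rep("ns", length(ids)))
    d <- stats::setNames(diff$direction, diff$peptide_id)
    out <- d[ids]
    out[is.na(out)] <- "ns"
    out
  }
  dirs <- dir_of(hits$peptide_id)
  tibble::tibble(
    precursor_acc = acc,
    position = seq_len(n),
    residue = if (!is.null(prec_seq)) strsplit(prec_seq, "")[[1]] else
      NA_character_,
    n_all = cover(hits),
    n_up = cover(hits[dirs == "up", , drop = FALSE]),
    n_down = cover(hits[dirs == "down", , drop = FALSE])
  )
}

#' Cleavage-residue frequency profile
#'
#' Counts residue frequencies at the four cleavage positions — N-terminal
#' cut P1 and P1', C-terminal cut P1 and P1' — over mapped peptides,
#' separately per differential direction when `diff` is supplied (plus the
#' pooled `all` stratum). Terminus sentinels are excluded. The dominant
#' residue per position is the count argmax, ties broken alphabetically.
#'
#' @param mappings [locate_peptides()] result.
#' @param diff Optional `pep_diff` result.
#' @return A `pep_cleavage` tibble: `direction`, `position` (factor with
#'   levels `Nterm-P1`, `Nterm-P1p`, `Cterm-P1`, `Cterm-P1p`), `residue`,
#'   `n`. Use [dominant_cleavage()] for the per-position argmax.
#' @export
cleavage_profile <- function(mappings, diff = NULL) {
  hits <- dplyr::filter(mappings, .data$hit)
  dirs <- if (is.null(diff)) {
    rep("all", nrow(hits))
  } else {
    d <- stats::setNames(diff$direction, diff$peptide_id)
    out <- d[hits$peptide_id]
    out[is.na(out)] <- "ns"
    out
  }
  pos_cols <- c("Nterm-P1" = "nterm_p1", "Nterm-P1p" = "nterm_p1p",
                "Cterm-P1" = "cterm_p1", "Cterm-P1p" = "cterm_p1p")
  strata <- unique(c("all", dirs))
  counts <- purrr::map_dfr(strata, function(g) {
    rows <- if (g == "all") hits else hits[dirs == g, , drop = FALSE]
    purrr::imap_dfr(pos_cols, function(col, pos) {
      res <- rows[[col]]
      res <- res[res %in% AA_ALPHABET]  # sentinels drop out
      tab <- table(factor(res, levels = AA_ALPHABET))
      tibble::tibble(direction = g, position = pos,
                     residue = names(tab), n = as.integer(tab))
    })
  })
  counts$position <- factor(counts$position, levels = names(pos_cols))
  class(counts) <- c("pep_cleavage", class(counts))
  counts
}

#' Dominant residue per cleavage position
#'
#' @param profile A [cleavage_profile()] result.
#' @return Tibble `direction`, `position`, `residue` (count argmax,
#'   alphabetical tie-break), `n`.
#' @export
dominant_cleavage <- function(profile) {
  tibble::as_tibble(profile) |>
    dplyr::group_by(.data$direction, .data$position) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$residue, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Precursors ranked by number of distinct peptides
#'
#' Descending count of distinct peptide sequences per precursor (restricted
#' to significant peptides when `diff` is given), ties broken by accession.
#'
#' @param mappings [locate_peptides()] result (or any data frame with
#'   `precursor_acc` and `sequence`).
#' @param diff Optional `pep_diff` result; restricts to significant
#'   peptides.
#' @return Tibble `precursor_acc`, `n_peptides`, `rank`.
#' @export
top_precursors <- function(mappings, diff = NULL) {
  d <- tibble::as_tibble(mappings)
  if (!is.null(diff)) {
    keep_ids <- diff$peptide_id[diff$significant]
    if ("peptide_id" %in% names(d)) {
      d <- dplyr::filter(d, .data$peptide_id %in% keep_ids)
    }
  }
  if (nrow(d) == 0L) {
    return(tibble::tibble(precursor_acc = character(0),
                          n_peptides = integer(0), rank = integer(0)))
  }
  d |>
    dplyr::distinct(.data$precursor_acc, .data$sequence) |>
    dplyr::count(.data$precursor_acc, name = "n_peptides") |>
    dplyr::arrange(dplyr::desc(.data$n_peptides), .data$precursor_acc) |>
    dplyr::mutate(rank = dplyr::row_number())
}
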