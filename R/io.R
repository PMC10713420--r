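# Readers/writers for the plain-text formats the pipeline touches: the
# quantified peptide TSV, precursor FASTA, domain-interval TSV and GMT gene
# sets. Coordinates are 1-based inclusive throughout; missing intensity is
# NA and is distinct from zero.

QUANT_FIXED_COLS <- c("peptide_id", "sequence", "precursor_acc", "gene",
                      "modifications")

parse_modifications <- function(cells) {
  purrr::map(cells, function(cell) {
    if (is.na(cell) || cell == "") {
      return(tibble::tibble(name = character(0), position = character(0)))
    }
    parts <- strsplit(cell, ";", fixed = TRUE)[[1]]
    m <- stringr::str_match(parts, "^([^@]+)@(N-term|[0-9]+)$")
    if (anyNA(m[, 1])) {
      stop("malformed modification token(s): ",
           paste(parts[is.na(m[, 1])], collapse = ", "), call. = FALSE)
    }
    tibble::tibble(name = m[, 2], position = m[, 3])
  })
}

format_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste0(m$name, "@", m$position, collapse = ";")
  }, character(1))
}

check_mod_positions <- function(mods, sequences) {
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (nrow(m) == 0L) next
    pos <- suppressWarnings(as.integer(m$position))
    numeric_pos <- !is.na(pos)
    bad <- numeric_pos & (pos < 1L | pos > nchar(sequences[i]))
    if (any(bad)) {
      stop("row ", i, ": modification position ", m$position[bad][1],
           " outside 1..", nchar(sequences[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a quantified peptide table
#'
#' Parses a TSV with fixed columns `peptide_id`, `sequence`,
#' `precursor_acc`, `gene`, `modifications` (semicolon-separated
#' `name@pos` tokens, `pos` a 1-based residue index or `N-term`), followed
#' by one intensity column per sample in `design`. Empty and `NA` intensity
#' cells become missing (`NA`), which downstream analyses treat as absent
#' quantitation, not as zero.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param design A data frame with columns `sample_id` and `group` (exactly
#'   two distinct groups).
#' @return A tibble with the fixed columns (modifications as a list-column
#'   of tibbles) plus one numeric column per sample.
#' @export
read_quant_table <- function(path, design) {
  design <- validate_design(design)
  raw <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_fixed <- setdiff(QUANT_FIXED_COLS, names(raw))
  if (length(missing_fixed)) {
    stop("quant table is missing column(s): ",
         paste(missing_fixed, collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), QUANT_FIXED_COLS)
  unknown <- setdiff(sample_cols, design$sample_id)
  if (length(unknown)) {
    stop("unknown sample column(s) not in design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(design$sample_id, sample_cols)
  if (length(absent)) {
    stop("design sample(s) absent from quant table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  seqs <- validate_sequences(raw$sequence, what = "quant table sequence")
  mods <- parse_modifications(raw$modifications)
  check_mod_positions(mods, seqs)
  out <- tibble::tibble(
    peptide_id = raw$peptide_id,
    sequence = seqs,
    precursor_acc = raw$precursor_acc,
    gene = dplyr::coalesce(raw$gene, ""),
    modifications = mods
  )
  for (s in design$sample_id) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    if (any(!is.na(v) & v < 0)) {
      stop("negative intensity in sample column ", s, call. = FALSE)
    }
    out[[s]] <- v
  }
  out
}

#' Write a quantified peptide table
#'
#' Inverse of [read_quant_table()]; finite intensities round-trip
#' bit-exactly (written with full precision) and missing values are written
#' as empty cells.
#'
#' @param quant A quant tibble as returned by [read_quant_table()].
#' @param path Output path.
#' @param provenance Logical; prepend a `#` provenance header line.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path, provenance = TRUE) {
  out <- quant
  out$modifications <- format_modifications(quant$modifications)
  sample_cols <- setdiff(names(out), QUANT_FIXED_COLS)
  for (s in sample_cols) {
    out[[s]] <- ifelse(is.na(out[[s]]), "",
                       formatC(out[[s]], digits = 17, format = "g"))
  }
  write_tsv_provenance(out, path, provenance = provenance)
}

#' Read precursor protein sequences from FASTA
#'
#' The first whitespace-delimited header token is the accession; an optional
#' `GN=<gene>` token supplies the gene symbol. Sequences are uppercased and
#' trailing `*` stop characters stripped.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `accession`, `gene`, `sequence`, `length`.
#' @export
read_precursor_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path, call. = FALSE)
  headers <- names(aa)
  acc <- stringr::str_extract(headers, "^\\S+")
  gene <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  gene[is.na(gene)] <- ""
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(sub("\\*+$", "", as.character(aa)))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for accession ", acc[nchar(seqs) == 0L][1],
         call. = FALSE)
  }
  validate_sequences(seqs, what = "precursor sequence")
  tibble::tibble(accession = unname(acc), gene = unname(gene),
                 sequence = unname(seqs), length = nchar(seqs))
}

#' Read Pfam-style domain intervals
#'
#' TSV with columns `accession`, `start`, `end`, `name`, `description`;
#' coordinates 1-based inclusive. When `precursors` is supplied, intervals
#' are validated against precursor lengths; rows for accessions absent from
#' the precursor table are kept but flagged with a warning.
#'
#' @param path TSV path.
#' @param precursors Optional precursor tibble from [read_precursor_fasta()].
#' @return A tibble `accession`, `start`, `end`, `name`, `description`,
#'   `attached` (logical; `FALSE` when the accession was not found).
#' @export
read_domain_table <- function(path, precursors = NULL) {
  d <- readr::read_tsv(path, comment = "#", progress = FALSE,
                       show_col_types = FALSE,
                       col_types = readr::cols(
                         accession = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         name = readr::col_character(),
                         description = readr::col_character()
                       ))
  if (any(d$start < 1L)) {
    stop("domain start < 1 (coordinates are 1-based inclusive)", call. = FALSE)
  }
  if (any(d$start > d$end)) {
    bad <- which(d$start > d$end)[1]
    stop("domain row ", bad, ": start ", d$start[bad], " > end ", d$end[bad],
         call. = FALSE)
  }
  d$attached <- TRUE
  if (!is.null(precursors)) {
    len <- stats::setNames(precursors$length, precursors$accession)
    known <- d$accession %in% names(len)
    if (any(!known)) {
      warning("domain rows for accession(s) absent from precursors kept ",
              "unattached: ",
              paste(unique(d$accession[!known]), collapse = ", "),
              call. = FALSE)
      d$attached <- known
    }
    over <- known & d$end > len[d$accession]
    if (any(over)) {
      stop("domain interval exceeds precursor length for ",
           paste(unique(d$accession[over]), collapse = ", "), call. = FALSE)
    }
  }
  d
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `set_id TAB description TAB member...` per line. Members
#' are de-duplicated, case preserved.
#'
#' @param path GMT path.
#' @return A tibble `set_id`, `description`, `members` (list-column of
#'   character vectors), `size`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("GMT line ", which(n < 3L)[1],
         " has fewer than 3 fields (needs set_id, description, >=1 member)",
         call. = FALSE)
  }
  tibble::tibble(
    set_id = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    members = purrr::map(fields, function(f) unique(f[-(1:2)])),
    size = vapply(fields, function(f) length(unique(f[-(1:2)])), integer(1))
  )
}

#' Validate a two-group sample design
#'
#' @param design Data frame with columns `sample_id`, `group`.
#' @return The design as a tibble with `group` as a factor whose level order
#'   follows first appearance (group 1 = reference; fold changes are
#'   group2/group1).
#' @export
validate_design <- function(design) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample_id", "group") %in% names(design)))
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  g <- unique(as.character(design$group))
  if (length(g) != 2L) {
    stop("design must have exactly two groups, got: ",
         paste(g, collapse = ", "), call. = FALSE)
  }
  design$group <- factor(as.character(design$group), levels = g)
  design
}

#' Write a TSV with a provenance header
#'
#' All pipeline outputs carry a single `#`-prefixed line recording the tool
#' version, a UTC timestamp and a digest of the run configuration, so any
#' table can be traced to the code and settings that made it.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param provenance Logical; write the header line.
#' @param config Optional list digested into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, provenance = TRUE, config = NULL) {
  if (provenance) {
    ver <- as.character(utils::packageVersion("pepdiff"))
    cfg <- if (is.null(config)) "none" else
      substr(rlang::hash(config), 1, 12)
    header <- sprintf("# pepdiff %s | %s | config=%s", ver,
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                      cfg)
    readr::write_lines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}
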