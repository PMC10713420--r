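# In-code fixtures shared across tests: a tiny two-group design, a small
# quant table written to disk on demand, and a pep_diff-shaped tibble built
# directly from known numbers.

tiny_design <- function(n_per_group = 2, groups = c("sham", "IR")) {
  tibble::tibble(
    sample_id = c(paste0(groups[1], "_", seq_len(n_per_group)),
                  paste0(groups[2], "_", seq_len(n_per_group))),
    group = rep(groups, each = n_per_group)
  )
}

write_tiny_quant <- function(path, design = tiny_design(),
                             sequences = c("VITIGNERF", "GDDLTVTNPK"),
                             mods = c("Oxidation@3;Acetyl@N-term", ""),
                             intensities = NULL) {
  n <- length(sequences)
  if (is.null(intensities)) {
    intensities <- matrix(seq_len(n * nrow(design)) * 10, nrow = n)
  }
  header <- c("peptide_id", "sequence", "precursor_acc", "gene",
              "modifications", design$sample_id)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(paste0("p", i), sequences[i], paste0("ACC", i), "",
            mods[i], intensities[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

# A minimal pep_diff-shaped object built from explicit values, for modules
# that consume differential results without rerunning the test.
make_diff <- function(peptide_id, sequence, precursor_acc, fold_change,
                      p_value, p_threshold = 0.01, fc_threshold = 2) {
  sig <- p_value < p_threshold & pmax(fold_change, 1 / fold_change) >= fc_threshold
  out <- tibble::tibble(
    peptide_id = peptide_id, sequence = sequence,
    precursor_acc = precursor_acc, gene = "",
    mean_g1 = 1, mean_g2 = fold_change,
    n_g1 = 6L, n_g2 = 6L,
    fold_change = fold_change, log2fc = log2(fold_change),
    t_stat = NA_real_, df = 10, p_value = p_value,
    q_value = stats::p.adjust(p_value, "BH"),
    zero_variance = FALSE, testable = TRUE, significant = sig,
    direction = ifelse(sig & fold_change > 1, "up",
                       ifelse(sig & fold_change < 1, "down", "ns"))
  )
  class(out) <- c("pep_diff", class(out))
  attr(out, "groups") <- c("g1", "g2")
  attr(out, "p_threshold") <- p_threshold
  attr(out, "fc_threshold") <- fc_threshold
  out
}
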