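# Synthetic peptidome generator with known ground truth. The default
# configuration emulates an iTRAQ-labeled two-group tissue peptidome:
# two groups of six samples, on the order of 10^3-10^4 peptides of length
# 9-99 from ~10^3 precursors, residue-biased proteolysis, log-normal
# abundances and a spiked fraction of >= 2-fold group effects.

# Derive a per-stage seed from the global seed so each stage is
# independently reproducible; kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 13L + stage * 7919L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe the emulated study design: n = 6 vs n = 6, ~10^3
#' precursors, peptides of 9-99 residues, log2 baseline abundance
#' Normal(20, 2), technical CV 0.2, 10% of peptides spiked at +/- 2 units
#' of log2 fold change (4-fold), 5% missing completely at random.
#'
#' @param n_precursors Number of precursor proteins.
#' @param precursor_length_range Integer range of precursor lengths (aa).
#' @param background `"uniform"` or `"vertebrate"` residue composition.
#' @param cleavage_preference Named numeric vector of relative cut odds at
#'   the C-terminal P1 residue (default uniform). Residues with zero odds
#'   are never cut after.
#' @param cut_rate Mean per-bond cut probability for a residue of odds 1.
#' @param peptide_length_range Kept fragment length range (aa).
#' @param n_samples_per_group Samples per group.
#' @param group_labels Two group names; group 2 carries the spikes.
#' @param spike_fraction Fraction of peptides with a true group effect.
#' @param spike_log2fc Absolute true log2 fold change of spiked peptides
#'   (sign Bernoulli 1/2).
#' @param baseline_mean,baseline_sd Log2 baseline abundance distribution.
#' @param cv Technical coefficient of variation on the linear scale.
#' @param missing_rate MCAR missingness rate.
#' @param seed Global integer seed; every stage derives its own stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_precursors = 1000,
                       precursor_length_range = c(150, 450),
                       background = c("uniform", "vertebrate"),
                       cleavage_preference = NULL,
                       cut_rate = 0.04,
                       peptide_length_range = c(9, 99),
                       n_samples_per_group = 6,
                       group_labels = c("sham", "IR"),
                       spike_fraction = 0.1,
                       spike_log2fc = 2,
                       baseline_mean = 20,
                       baseline_sd = 2,
                       cv = 0.2,
                       missing_rate = 0.05,
                       seed = 1) {
  background <- match.arg(background)
  if (is.null(cleavage_preference)) {
    cleavage_preference <- stats::setNames(rep(1, 20), AA_ALPHABET)
  }
  stopifnot(
    all(cleavage_preference >= 0), any(cleavage_preference > 0),
    peptide_length_range[1] <= peptide_length_range[2],
    precursor_length_range[1] <= precursor_length_range[2],
    spike_fraction >= 0, spike_fraction <= 1,
    missing_rate >= 0, missing_rate < 1,
    cv >= 0, n_samples_per_group >= 2, length(group_labels) == 2
  )
  cfg <- list(
    n_precursors = n_precursors,
    precursor_length_range = as.integer(precursor_length_range),
    background = background,
    cleavage_preference = cleavage_preference[AA_ALPHABET],
    cut_rate = cut_rate,
    peptide_length_range = as.integer(peptide_length_range),
    n_samples_per_group = as.integer(n_samples_per_group),
    group_labels = group_labels,
    spike_fraction = spike_fraction,
    spike_log2fc = spike_log2fc,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    cv = cv,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  cfg$cleavage_preference[is.na(cfg$cleavage_preference)] <- 0
  names(cfg$cleavage_preference) <- AA_ALPHABET
  class(cfg) <- "sim_config"
  cfg
}

# length-safe uniform integer draw on [lo, hi] (sample() would misread a
# scalar range)
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

sim_background_freq <- function(config) {
  if (config$background == "uniform") AA_FREQ_UNIFORM else AA_FREQ_VERTEBRATE
}

#' Simulate precursor proteins
#'
#' I.i.d. residues from the configured background composition, lengths
#' uniform over the configured range, and 0-3 random non-overlapping
#' domain intervals per precursor. Byte-identical under the same seed.
#'
#' @param config A [sim_config()].
#' @return A list: `precursors` (tibble `accession`, `gene`, `sequence`,
#'   `length`) and `domains` (tibble as from [read_domain_table()]).
#' @export
sim_precursors <- function(config) {
  freq <- sim_background_freq(config)
  with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_precursors
    lens <- sample_range(config$precursor_length_range[1],
                         config$precursor_length_range[2], n)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freq),
            collapse = "")
    }, character(1))
    prec <- tibble::tibble(
      accession = sprintf("SIM%04d", seq_len(n)),
      gene = sprintf("Gene%04d", seq_len(n)),
      sequence = seqs,
      length = lens
    )
    domains <- purrr::map_dfr(seq_len(n), function(i) {
      n_dom <- sample(0:3, 1)
      if (n_dom == 0L) return(NULL)
      L <- lens[i]
      taken <- logical(L)
      out <- list()
      for (d in seq_len(n_dom)) {
        w <- sample_range(10L, min(80L, max(10L, L %/% 2L)), 1L)
        if (w >= L) next
        s <- sample_range(1L, L - w, 1L)
        idx <- s:(s + w - 1L)
        if (any(taken[idx])) next
        taken[idx] <- TRUE
        out[[length(out) + 1L]] <- tibble::tibble(
          accession = prec$accession[i], start = s, end = s + w - 1L,
          name = sprintf("DOM%d", length(out) + 1L),
          description = "simulated domain"
        )
      }
      dplyr::bind_rows(out)
    })
    list(precursors = prec, domains = domains)
  })
}

#' Simulate residue-biased proteolysis
#'
#' Each peptide bond is cut independently with probability
#' `cut_rate * odds[P1] / mean(odds over the alphabet)` (capped at 1),
#' where P1 is the residue N-terminal to the bond — a memoryless model of
#' protease specificity. Fragments outside `peptide_length_range` are
#' discarded; each kept fragment's true location and flanking cleavage
#' residues are recorded.
#'
#' @param precursors Precursor tibble.
#' @param config A [sim_config()].
#' @return A tibble of peptide skeletons: `peptide_id`, `sequence`,
#'   `precursor_acc`, `start`, `end`, `nterm_p1_true`, `cterm_p1_true`
#'   (sentinels at protein termini).
#' @export
sim_digest <- function(precursors, config) {
  pref <- config$cleavage_preference
  p_bond <- pmin(config$cut_rate * pref / mean(pref), 1)
  lr <- config$peptide_length_range
  with_seed(stage_seed(config$seed, 2L), {
    frags <- purrr::map_dfr(seq_len(nrow(precursors)), function(i) {
      s <- precursors$sequence[i]
      res <- strsplit(s, "")[[1]]
      L <- length(res)
      if (L < 2L) return(NULL)
      cut_after <- which(stats::runif(L - 1) < p_bond[res[-L]])
      starts <- c(1L, cut_after + 1L)
      ends <- c(cut_after, L)
      keep <- (ends - starts + 1L) >= lr[1] & (ends - starts + 1L) <= lr[2]
      if (!any(keep)) return(NULL)
      tibble::tibble(
        sequence = substring(s, starts[keep], ends[keep]),
        precursor_acc = precursors$accession[i],
        start = starts[keep], end = ends[keep],
        nterm_p1_true = ifelse(starts[keep] == 1L, NTERM_SENTINEL,
                               res[pmax(starts[keep] - 1L, 1L)]),
        cterm_p1_true = res[ends[keep]]
      )
    })
    # a fragment flush with the protein C-terminus ends at no cut bond
    plen <- stats::setNames(nchar(precursors$sequence), precursors$accession)
    frags$cterm_p1_true[frags$end == plen[frags$precursor_acc]] <-
      CTERM_SENTINEL
    frags$peptide_id <- sprintf("pep%06d", seq_len(nrow(frags)))
    dplyr::relocate(frags, "peptide_id")
  })
}

#' Simulate random peptide skeletons without a digest
#'
#' Convenience generator for abundance-model calibration at an exact
#' peptide count: random sequences with lengths uniform over the peptide
#' range, assigned round-robin to pseudo-precursors.
#'
#' @param n_peptides Number of peptides.
#' @param config A [sim_config()].
#' @return A skeleton tibble compatible with [sim_abundance()].
#' @export
sim_peptide_skeletons <- function(n_peptides, config) {
  freq <- sim_background_freq(config)
  lr <- config$peptide_length_range
  with_seed(stage_seed(config$seed, 5L), {
    lens <- sample_range(lr[1], lr[2], n_peptides)
    tibble::tibble(
      peptide_id = sprintf("pep%06d", seq_len(n_peptides)),
      sequence = vapply(lens, function(L) {
        paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freq),
              collapse = "")
      }, character(1)),
      precursor_acc = sprintf("SIM%04d",
                              ((seq_len(n_peptides) - 1L) %%
                                 max(1L, n_peptides %/% 8L)) + 1L)
    )
  })
}

#' Simulate two-group reporter intensities with spiked effects
#'
#' Per-peptide baseline log2 abundance ~ Normal(`baseline_mean`,
#' `baseline_sd`); a Bernoulli(`spike_fraction`) subset receives a group-2
#' mean shift of +/- `spike_log2fc` (sign Bernoulli 1/2); log-normal
#' technical noise with the configured linear-scale CV is added per sample;
#' cells go missing completely at random at `missing_rate`.
#'
#' @param skeletons Peptide skeleton tibble ([sim_digest()] or
#'   [sim_peptide_skeletons()]).
#' @param config A [sim_config()].
#' @return A list: `quant` (quant tibble with modification list-column and
#'   one intensity column per sample), `design` (sample design tibble),
#'   `truth` (tibble `peptide_id`, `spiked`, `true_log2fc`, plus any
#'   location columns carried from the skeletons).
#' @export
sim_abundance <- function(skeletons, config) {
  n <- nrow(skeletons)
  ns <- config$n_samples_per_group
  design <- tibble::tibble(
    sample_id = c(paste0(config$group_labels[1], "_", seq_len(ns)),
                  paste0(config$group_labels[2], "_", seq_len(ns))),
    group = rep(config$group_labels, each = ns)
  )
  sigma_log2 <- sqrt(log(1 + config$cv^2)) / log(2)
  with_seed(stage_seed(config$seed, 3L), {
    mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    spiked <- stats::runif(n) < config$spike_fraction
    sign_ <- ifelse(stats::runif(n) < 0.5, 1, -1)
    true_log2fc <- ifelse(spiked, sign_ * config$spike_log2fc, 0)
    quant <- tibble::tibble(
      peptide_id = skeletons$peptide_id,
      sequence = skeletons$sequence,
      precursor_acc = skeletons$precursor_acc,
      gene = "",
      modifications = purrr::map(seq_len(n), ~ tibble::tibble(
        name = character(0), position = character(0)))
    )
    for (j in seq_len(nrow(design))) {
      shift <- if (design$group[j] == config$group_labels[2]) true_log2fc else 0
      v <- 2^(mu + shift + stats::rnorm(n, 0, sigma_log2))
      if (config$missing_rate > 0) {
        v[stats::runif(n) < config$missing_rate] <- NA_real_
      }
      quant[[design$sample_id[j]]] <- v
    }
    truth <- dplyr::bind_cols(
      tibble::tibble(peptide_id = skeletons$peptide_id, spiked = spiked,
                     true_log2fc = true_log2fc),
      skeletons[setdiff(names(skeletons),
                        c("peptide_id", "sequence", "precursor_acc"))]
    )
    list(quant = quant, design = design, truth = truth)
  })
}

#' Simulate a complete peptidome experiment
#'
#' Chains [sim_precursors()], [sim_digest()] and [sim_abundance()] under
#' one global seed (each stage draws from its own derived stream, so stages
#' are independently reproducible).
#'
#' @param config A [sim_config()].
#' @return A list: `precursors`, `domains`, `quant`, `design`, `truth`,
#'   `config`.
#' @export
sim_peptidome <- function(config = sim_config()) {
  pp <- sim_precursors(config)
  skel <- sim_digest(pp$precursors, config)
  ab <- sim_abundance(skel, config)
  list(precursors = pp$precursors, domains = pp$domains,
       quant = ab$quant, design = ab$design, truth = ab$truth,
       config = config)
}
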