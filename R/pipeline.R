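# End-to-end orchestration: simulate or ingest -> normalize -> differential
# expression -> mapping -> physicochemical panel -> enrichment -> candidate
# ranking, with provenance-stamped TSV outputs and a summary JSON.

log_stage <- function(stage, msg) {
  message(sprintf("%s INFO %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  stage, msg))
}

run_stage <- function(stage, expr) {
  log_stage(stage, "start")
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Write via a .partial file so an interrupted stage never leaves a
# truncated table under the final name.
write_output <- function(x, outdir, name, config) {
  final <- file.path(outdir, name)
  partial <- paste0(final, ".partial")
  write_tsv_provenance(x, partial, config = config)
  file.rename(partial, final)
  invisible(final)
}

#' Pipeline configuration
#'
#' Either point `quant_path`/`fasta_path`/... at input files, or supply a
#' [sim_config()] as `sim` to run on simulated data with known truth.
#'
#' @param outdir Output directory (created if needed).
#' @param quant_path,fasta_path,domains_path,gmt_path Input file paths
#'   (`gmt_path` and `domains_path` optional).
#' @param design A design data frame, required with `quant_path`.
#' @param sim Optional [sim_config()]; replaces the file inputs.
#' @param p_threshold,fc_threshold Differential gates.
#' @param normalize `"median-ratio"` or `"none"`.
#' @param weights Candidate-ranking weights ([rank_candidates()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            quant_path = NULL, fasta_path = NULL,
                            domains_path = NULL, gmt_path = NULL,
                            design = NULL, sim = NULL,
                            p_threshold = 0.01, fc_threshold = 2,
                            normalize = "median-ratio",
                            weights = c(p = 1, fc = 1, half_life = 1,
                                        gravy = 1, stable = 1)) {
  if (is.null(sim)) {
    for (p in c(quant_path, fasta_path, domains_path, gmt_path)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("input path does not exist: ", p, call. = FALSE)
      }
    }
    if (is.null(quant_path) || is.null(fasta_path) || is.null(design)) {
      stop("need quant_path, fasta_path and design (or a sim config)",
           call. = FALSE)
    }
  }
  structure(list(outdir = outdir, quant_path = quant_path,
                 fasta_path = fasta_path, domains_path = domains_path,
                 gmt_path = gmt_path, design = design, sim = sim,
                 p_threshold = p_threshold, fc_threshold = fc_threshold,
                 normalize = normalize, weights = weights),
            class = "pipeline_config")
}

#' Run the full peptidomics pipeline
#'
#' Executes all stages in dependency order, writing provenance-stamped TSV
#' tables plus a `summary.json` of headline numbers to the output
#' directory. Any stage failure aborts with the stage name in the error. On
#' identical inputs and configuration the summary JSON is identical across
#' runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`quant`, `diff`,
#'   `mappings`, `profiles`, `enrichment`, `candidates`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  dat <- run_stage("load", {
    if (!is.null(config$sim)) {
      sim_peptidome(config$sim)
    } else {
      design <- validate_design(config$design)
      precursors <- read_precursor_fasta(config$fasta_path)
      domains <- if (!is.null(config$domains_path)) {
        read_domain_table(config$domains_path, precursors)
      } else {
        NULL
      }
      list(quant = read_quant_table(config$quant_path, design),
           design = design, precursors = precursors, domains = domains,
           truth = NULL)
    }
  })

  quant <- run_stage("normalize", {
    normalize_intensities(dat$quant, dat$design, method = config$normalize)
  })

  diff <- run_stage("diffexp", {
    test_peptides(quant, dat$design, p_threshold = config$p_threshold,
                  fc_threshold = config$fc_threshold)
  })
  write_output(tidy.pep_diff(diff), config$outdir, "diff_results.tsv", config)
  write_output(volcano_table(diff), config$outdir, "volcano.tsv", config)

  mappings <- run_stage("map", {
    m <- locate_peptides(quant, dat$precursors)
    if (!is.null(dat$domains)) m <- annotate_domains(m, dat$domains)
    m
  })
  flat <- mappings |>
    dplyr::select(-dplyr::any_of(c("all_starts", "domains_containing",
                                   "domains_overlapping")))
  write_output(flat, config$outdir, "mappings.tsv", config)
  profile_tbl <- run_stage("cleavage", cleavage_profile(mappings, diff))
  write_output(tibble::as_tibble(profile_tbl), config$outdir,
               "cleavage_profile.tsv", config)

  profiles <- run_stage("physchem", {
    physchem_profile(quant[diff$significant, , drop = FALSE])
  })
  write_output(profiles, config$outdir, "physchem.tsv", config)

  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    enrichment <- run_stage("enrich", {
      sets <- read_gene_sets(config$gmt_path)
      ora(unique(diff$precursor_acc[diff$significant]), sets,
          unique(quant$precursor_acc))
    })
    write_output(enrichment, config$outdir, "enrichment.tsv", config)
  }

  tp <- top_precursors(diff, diff)
  candidates <- NULL
  if (nrow(tp) > 0L) {
    candidates <- run_stage("rank", {
      rank_candidates(build_candidate_table(diff, profiles,
                                            tp$precursor_acc[1]),
                      weights = config$weights)
    })
    write_output(candidates, config$outdir, "candidates.tsv", config)
  }

  g <- glance.pep_diff(diff)
  summary <- list(
    n_peptides = nrow(quant),
    n_testable = g$n_testable,
    n_significant = g$n_significant,
    n_up = g$n_up,
    n_down = g$n_down,
    top_precursor = if (nrow(tp)) tp$precursor_acc[1] else NA,
    top_precursor_n_peptides = if (nrow(tp)) tp$n_peptides[1] else 0L,
    candidates = if (is.null(candidates)) list() else
      candidates[, c("peptide_id", "sequence", "rank_score", "rank")]
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", sprintf("%d peptides, %d significant", nrow(quant),
                            g$n_significant))
  invisible(list(quant = quant, design = dat$design, diff = diff,
                 mappings = mappings, profiles = profiles,
                 enrichment = enrichment, candidates = candidates,
                 summary = summary))
}
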