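# Two-group differential peptide expression and dataset-level summaries.
# Testing follows the reporter-ion convention: Student's pooled-variance
# two-tailed t-test on log2 intensities, fold change as the ratio of group
# geometric means, and a dual gate (p below threshold AND max(FC, 1/FC) at
# or above the fold threshold). Missing values are excluded per peptide.

intensity_matrix <- function(quant, design) {
  m <- as.matrix(quant[, design$sample_id, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- quant$peptide_id
  m
}

#' Median-ratio normalization of sample intensities
#'
#' Rescales each sample column so that sample medians, computed over the
#' peptides quantified in every sample (complete cases), are equal to the
#' median of those medians. Method `"none"` passes the data through. A
#' matrix already median-equal is a fixed point.
#'
#' @param quant A quant tibble ([read_quant_table()]).
#' @param design Sample design ([validate_design()]).
#' @param method `"median-ratio"` or `"none"`.
#' @return The quant tibble with rescaled sample columns; scale factors in
#'   attribute `"scale_factors"`.
#' @export
normalize_intensities <- function(quant, design,
                                  method = c("median-ratio", "none")) {
  method <- match.arg(method)
  design <- validate_design(design)
  if (method == "none") return(quant)
  m <- intensity_matrix(quant, design)
  if (any(colSums(!is.na(m)) == 0L)) {
    bad <- design$sample_id[colSums(!is.na(m)) == 0L]
    stop("sample(s) with zero quantified peptides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(m)
  if (!any(cc)) {
    stop("no peptides quantified in all samples; cannot compute ",
         "median-ratio factors", call. = FALSE)
  }
  med <- apply(m[cc, , drop = FALSE], 2, stats::median)
  if (any(med <= 0)) {
    stop("non-positive sample median; cannot scale", call. = FALSE)
  }
  target <- stats::median(med)
  factors <- target / med
  out <- quant
  for (j in seq_along(design$sample_id)) {
    out[[design$sample_id[j]]] <- quant[[design$sample_id[j]]] * factors[j]
  }
  attr(out, "scale_factors") <- stats::setNames(factors, design$sample_id)
  out
}

# Vectorised pooled-variance two-sample t-test on the rows of two matrices
# (NA-aware). Returns t, df, p; zero pooled variance gives p = 1 with a flag.
row_t_pooled <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  zero_var <- is.finite(sp2) & sp2 <= 0
  t_stat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[zero_var & m1 == m2] <- 1
  t_stat[zero_var & m1 == m2] <- 0
  list(mean1 = unname(m1), mean2 = unname(m2), n1 = unname(n1),
       n2 = unname(n2), t = unname(t_stat), df = unname(df),
       p = unname(p), zero_variance = unname(zero_var))
}

#' Two-group differential peptide expression
#'
#' Student's (pooled-variance) two-tailed t-test per peptide, on log2
#' intensities by default. Fold change is the ratio of group-2 over
#' group-1 means: geometric means when testing on the log scale, arithmetic
#' otherwise. A peptide is significant when `p_value < p_threshold` and
#' `max(FC, 1/FC) >= fc_threshold`. Peptides with fewer than two non-missing
#' values in either group are reported with `testable = FALSE`, never
#' silently dropped. Zero within-group variance in both groups gives
#' `p = 1` with `zero_variance = TRUE`. Benjamini-Hochberg q-values are
#' appended for transparency; the significance gate uses raw p.
#'
#' @param quant Quant tibble ([read_quant_table()]).
#' @param design Sample design; group order in the design defines the fold
#'   direction (group2 / group1).
#' @param p_threshold Raw p-value gate (default 0.01).
#' @param fc_threshold Linear fold-change gate applied as
#'   `max(FC, 1/FC) >= fc_threshold` (default 2).
#' @param log_transform Test on log2 intensities (default `TRUE`). Zeros are
#'   offset by half the smallest positive intensity before logging.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return A `pep_diff` tibble: `peptide_id`, `sequence`, `precursor_acc`,
#'   `gene`, `mean_g1`, `mean_g2`, `n_g1`, `n_g2`, `fold_change`, `log2fc`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `zero_variance`, `testable`,
#'   `significant`, `direction` (`up`/`down`/`ns`).
#' @export
test_peptides <- function(quant, design, p_threshold = 0.01,
                          fc_threshold = 2, log_transform = TRUE,
                          welch = FALSE) {
  design <- validate_design(design)
  stopifnot(p_threshold > 0, fc_threshold >= 1)
  m <- intensity_matrix(quant, design)
  groups <- levels(design$group)
  s1 <- design$sample_id[design$group == groups[1]]
  s2 <- design$sample_id[design$group == groups[2]]
  if (log_transform) {
    pos <- m[!is.na(m) & m > 0]
    offset <- if (length(pos)) min(pos) / 2 else 1
    ml <- log2(ifelse(m <= 0, offset, m))
  } else {
    ml <- m
  }
  x1 <- ml[, s1, drop = FALSE]
  x2 <- ml[, s2, drop = FALSE]
  tt <- if (welch) row_t_welch(x1, x2) else row_t_pooled(x1, x2)
  testable <- tt$n1 >= 2L & tt$n2 >= 2L
  if (log_transform) {
    mean_g1 <- 2^tt$mean1
    mean_g2 <- 2^tt$mean2
  } else {
    mean_g1 <- tt$mean1
    mean_g2 <- tt$mean2
  }
  fc <- mean_g2 / mean_g1
  log2fc <- log2(fc)
  p <- ifelse(testable, tt$p, NA_real_)
  sig <- testable & !is.na(p) & p < p_threshold &
    pmax(fc, 1 / fc) >= fc_threshold
  direction <- dplyr::case_when(
    sig & fc > 1 ~ "up",
    sig & fc < 1 ~ "down",
    .default = "ns"
  )
  out <- tibble::tibble(
    peptide_id = quant$peptide_id,
    sequence = quant$sequence,
    precursor_acc = quant$precursor_acc,
    gene = if ("gene" %in% names(quant)) quant$gene else "",
    mean_g1 = mean_g1, mean_g2 = mean_g2,
    n_g1 = tt$n1, n_g2 = tt$n2,
    fold_change = fc, log2fc = log2fc,
    t_stat = ifelse(testable, tt$t, NA_real_),
    df = ifelse(testable, tt$df, NA_real_),
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    zero_variance = tt$zero_variance,
    testable = testable,
    significant = sig,
    direction = direction
  )
  class(out) <- c("pep_diff", class(out))
  attr(out, "groups") <- groups
  attr(out, "p_threshold") <- p_threshold
  attr(out, "fc_threshold") <- fc_threshold
  out
}

row_t_welch <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero_var <- is.finite(se2) & se2 <= 0
  t_stat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[zero_var & m1 == m2] <- 1
  t_stat[zero_var & m1 == m2] <- 0
  list(mean1 = unname(m1), mean2 = unname(m2), n1 = unname(n1),
       n2 = unname(n2), t = unname(t_stat), df = unname(df),
       p = unname(p), zero_variance = unname(zero_var))
}

#' @method glance pep_diff
#' @export
glance.pep_diff <- function(x, ...) {
  tibble::tibble(
    n_peptides = nrow(x),
    n_testable = sum(x$testable),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    p_threshold = attr(x, "p_threshold"),
    fc_threshold = attr(x, "fc_threshold")
  )
}

#' @method tidy pep_diff
#' @export
tidy.pep_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pep_diff")
  out
}

#' Peptide length distribution
#'
#' @param quant A data frame with a `sequence` column.
#' @return A list: `histogram` (tibble `length`, `n` over the integer range
#'   observed) and `mean_length` (2 decimals).
#' @export
peptide_length_summary <- function(quant) {
  len <- nchar(quant$sequence)
  histogram <- tibble::as_tibble(table(length = len)) |>
    dplyr::mutate(length = as.integer(.data$length)) |>
    dplyr::rename(n = "n")
  list(histogram = histogram, mean_length = round(mean(len), 2))
}

#' Unique peptides per precursor
#'
#' A peptide sequence counts once per precursor (duplicate identifications
#' collapse). `share_multi` is the percentage of precursors carrying at
#' least two unique peptide sequences.
#'
#' @param quant A data frame with `sequence` and `precursor_acc` columns.
#' @return A list: `per_precursor` (tibble `precursor_acc`, `n_unique`) and
#'   `share_multi` (percent, 2 decimals).
#' @export
unique_peptide_counts <- function(quant) {
  per <- tibble::as_tibble(quant) |>
    dplyr::distinct(.data$precursor_acc, .data$sequence) |>
    dplyr::count(.data$precursor_acc, name = "n_unique") |>
    dplyr::arrange(dplyr::desc(.data$n_unique), .data$precursor_acc)
  list(per_precursor = per,
       share_multi = round(100 * mean(per$n_unique >= 2), 2))
}

#' Per-group coefficient of variation
#'
#' Sample CV (sd/mean, n-1 denominator) per peptide per group on linear
#' intensities, missing values excluded; scale-invariant within a group.
#'
#' @param quant Quant tibble.
#' @param design Sample design.
#' @return A tibble `peptide_id`, `group`, `n`, `cv` (NA when fewer than two
#'   non-missing values or zero mean).
#' @export
group_cv <- function(quant, design) {
  design <- validate_design(design)
  m <- intensity_matrix(quant, design)
  purrr::map_dfr(levels(design$group), function(g) {
    mg <- m[, design$sample_id[design$group == g], drop = FALSE]
    n <- rowSums(!is.na(mg))
    mu <- rowMeans(mg, na.rm = TRUE)
    sd_ <- sqrt(rowSums((mg - mu)^2, na.rm = TRUE) / (n - 1))
    tibble::tibble(peptide_id = quant$peptide_id, group = g, n = unname(n),
                   cv = unname(ifelse(n >= 2 & mu != 0, sd_ / mu, NA_real_)))
  })
}

#' Principal component analysis of samples
#'
#' Complete-case PCA: peptides quantified in every sample are centered per
#' peptide (on log2 intensities by default) and decomposed by SVD. Samples
#' are the observations. Loading-column signs are fixed by making each
#' column's largest-magnitude entry positive.
#'
#' @param quant Quant tibble.
#' @param design Sample design.
#' @param k Number of components.
#' @param log_transform Use log2 intensities.
#' @return A `pep_pca` object: list with `scores` (samples x k, with
#'   `sample_id`/`group`), `loadings` (peptides x k, orthonormal columns),
#'   `explained_variance_ratio` (length k, non-increasing), `n_peptides`.
#' @export
peptide_pca <- function(quant, design, k = 2, log_transform = TRUE) {
  design <- validate_design(design)
  m <- intensity_matrix(quant, design)
  if (log_transform) {
    pos <- m[!is.na(m) & m > 0]
    offset <- if (length(pos)) min(pos) / 2 else 1
    m <- log2(ifelse(m <= 0, offset, m))
  }
  cc <- stats::complete.cases(m)
  x <- m[cc, , drop = FALSE]
  if (k > min(dim(x))) {
    stop("k = ", k, " exceeds min(n peptides, n samples) = ", min(dim(x)),
         call. = FALSE)
  }
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  loadings <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$v[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  evr <- sv$d^2 / sum(sv$d^2)
  out <- list(
    scores = tibble::tibble(sample_id = design$sample_id,
                            group = as.character(design$group)) |>
      dplyr::bind_cols(tibble::as_tibble(scores,
                                         .name_repair = ~ paste0("PC", seq_len(k)))),
    loadings = loadings,
    explained_variance_ratio = evr[seq_len(k)],
    n_peptides = nrow(x)
  )
  class(out) <- "pep_pca"
  out
}

#' @export
print.pep_pca <- function(x, ...) {
  cat("Peptide PCA:", x$n_peptides, "complete-case peptides,",
      nrow(x$scores), "samples\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      "\n")
  print(x$scores)
  invisible(x)
}

#' Volcano table
#'
#' @param diff A [test_peptides()] result.
#' @return Tibble `peptide_id`, `log2fc`, `neg_log10_p`, `class`
#'   (up/down/ns); the partition is exhaustive and exclusive.
#' @export
volcano_table <- function(diff) {
  stopifnot(inherits(diff, "pep_diff"))
  tibble::tibble(
    peptide_id = diff$peptide_id,
    log2fc = diff$log2fc,
    neg_log10_p = -log10(diff$p_value),
    class = diff$direction
  )
}

#' Z-scored heatmap matrix with hierarchical row order
#'
#' Rows (significant peptides by default) are z-scored on log2 intensities
#' and ordered by average-linkage hierarchical clustering of Euclidean
#' distances between z-score rows.
#'
#' @param quant Quant tibble.
#' @param design Sample design.
#' @param diff Optional [test_peptides()] result; when given, only
#'   significant peptides are included.
#' @return A tibble `peptide_id` plus one z-score column per sample, rows in
#'   dendrogram order; the `hclust` object in attribute `"hclust"`.
#' @export
heatmap_table <- function(quant, design, diff = NULL) {
  design <- validate_design(design)
  keep <- rep(TRUE, nrow(quant))
  if (!is.null(diff)) {
    keep <- quant$peptide_id %in% diff$peptide_id[diff$significant]
  }
  m <- intensity_matrix(quant[keep, , drop = FALSE], design)
  pos <- m[!is.na(m) & m > 0]
  offset <- if (length(pos)) min(pos) / 2 else 1
  m <- log2(ifelse(m <= 0, offset, m))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  z <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(z), method = "average")
  z <- z[hc$order, , drop = FALSE]
  out <- tibble::as_tibble(z, rownames = "peptide_id")
  attr(out, "hclust") <- hc
  out
}
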