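make_quant <- function(values, design, sequences = NULL) {
  n <- nrow(values)
  if (is.null(sequences)) sequences <- strrep("ACDEFGHIK", seq_len(n))
  q <- tibble::tibble(
    peptide_id = paste0("p", seq_len(n)),
    sequence = substr(sequences, 1, 99),
    precursor_acc = paste0("ACC", seq_len(n)),
    gene = "",
    modifications = replicate(n, tibble::tibble(name = character(0),
                                                position = character(0)),
                              simplify = FALSE)
  )
  for (j in seq_len(nrow(design))) q[[design$sample_id[j]]] <- values[, j]
  q
}

test_that("median-ratio normalization equalizes medians and recovers factors", {
  design <- tiny_design(3)
  set.seed(10)
  # identical columns: every sample shares the same pre-scaling median
  base <- matrix(rep(2^stats::rnorm(50, 10, 1), 6), nrow = 50)
  truth_factors <- c(1, 2, 0.5, 4, 1.5, 0.8)
  skewed <- sweep(base, 2, truth_factors, `*`)
  q <- normalize_intensities(make_quant(skewed, design), design)
  m <- as.matrix(q[design$sample_id])
  med <- apply(m, 2, stats::median)
  expect_equal(max(med) - min(med), 0, tolerance = 1e-9)
  # recovered factors undo the injected ones up to a global scale
  f <- attr(q, "scale_factors")
  expect_equal(f * truth_factors / (f * truth_factors)[1], rep(1, 6),
               tolerance = 1e-6, ignore_attr = TRUE)
  # fixed point: re-normalizing changes nothing
  q2 <- normalize_intensities(q, design)
  expect_equal(as.matrix(q2[design$sample_id]), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a fully missing sample is an error
  broken <- skewed; broken[, 2] <- NA
  expect_error(normalize_intensities(make_quant(broken, design), design),
               "zero quantified")
})

test_that("the t-test matches the closed-form pooled oracle on a toy table", {
  design <- tiny_design(3)
  vals <- matrix(c(8, 9, 10, 16, 18, 20), nrow = 1)
  q <- make_quant(vals, design)
  d <- test_peptides(q, design)
  # independent oracle: pooled t on the log2 values
  oracle <- stats::t.test(log2(c(16, 18, 20)), log2(c(8, 9, 10)),
                          var.equal = TRUE)
  expect_equal(d$t_stat, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(d$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(d$df, 4)
  # fold change is the ratio of geometric means
  expect_equal(d$fold_change,
               2^(mean(log2(c(16, 18, 20))) - mean(log2(c(8, 9, 10)))))
  expect_equal(d$direction, "up")
})

test_that("degenerate and identical groups are handled without crashing", {
  design <- tiny_design(3)
  vals <- rbind(c(5, 5, 5, 5, 5, 5),      # zero variance, equal means
                c(4, 4, 4, 8, 8, 8),      # zero variance, different means
                c(3, 4, 5, 3, 4, 5))      # identical groups
  d <- test_peptides(make_quant(vals, design), design)
  expect_equal(d$p_value[1], 1)
  expect_true(d$zero_variance[1])
  expect_equal(d$fold_change[3], 1)
  expect_equal(d$direction[3], "ns")
  # insufficient replication is reported, not dropped
  vals2 <- rbind(c(1, NA, NA, 2, 3, 4))
  d2 <- test_peptides(make_quant(vals2, design), design)
  expect_equal(nrow(d2), 1)
  expect_false(d2$testable)
  expect_true(is.na(d2$p_value))
})

test_that("testing is invariant to sample order and group relabeling", {
  design <- tiny_design(3)
  set.seed(11)
  vals <- matrix(2^stats::rnorm(120, 12, 1), nrow = 20)
  q <- make_quant(vals, design)
  d1 <- test_peptides(q, design)
  # permute samples while keeping the group-appearance order (the reference
  # group is defined by first appearance in the design)
  perm <- c(3, 1, 2, 6, 4, 5)
  d2 <- test_peptides(q, design[perm, ])
  expect_equal(d2$p_value, d1$p_value)
  expect_equal(d2$fold_change, d1$fold_change)
  relabeled <- design
  relabeled$group <- ifelse(design$group == "sham", "ctrl", "treat")
  d3 <- test_peptides(q, relabeled)
  expect_equal(d3$p_value, d1$p_value)
  expect_equal(d3$significant, d1$significant)
})

test_that("length summary matches a direct count on the printed table", {
  t1 <- pep_table1()
  s <- peptide_length_summary(t1)
  expect_equal(s$mean_length, round(sum(nchar(t1$sequence)) / 40, 2))
  expect_equal(sum(s$histogram$n), 40)
  one <- peptide_length_summary(tibble::tibble(sequence = "VITIGNERF"))
  expect_equal(one$mean_length, 9)
})

test_that("unique peptide counts collapse duplicates and compute the share", {
  q <- tibble::tibble(
    precursor_acc = c("A", "A", "A", "B", "B", "C"),
    sequence = c("VITIGNERF", "VITIGNERF", "GDDLTVTNPK",
                 "ALDFIASK", "ITAVPTLLK", "GTVVTGTLER")
  )
  u <- unique_peptide_counts(q)
  expect_equal(u$per_precursor$n_unique[u$per_precursor$precursor_acc == "A"], 2L)
  expect_equal(u$share_multi, round(100 * 2 / 3, 2))
  solo <- unique_peptide_counts(tibble::tibble(precursor_acc = c("A", "B"),
                                               sequence = c("SEQA", "SEQB")))
  expect_equal(solo$share_multi, 0)
})

test_that("group CV matches the hand formula and is scale-invariant", {
  design <- tiny_design(3)
  vals <- rbind(c(1, 2, 3, 10, 20, 30), c(5, 5, 5, 7, 7, 7))
  cv <- group_cv(make_quant(vals, design), design)
  expect_equal(cv$cv[cv$peptide_id == "p1" & cv$group == "sham"],
               stats::sd(1:3) / mean(1:3))
  # scaling one group by 10 leaves its CV unchanged
  expect_equal(cv$cv[cv$peptide_id == "p1" & cv$group == "IR"],
               stats::sd(1:3) / mean(1:3))
  expect_equal(cv$cv[cv$peptide_id == "p2" & cv$group == "sham"], 0)
})

test_that("PCA agrees with an eigendecomposition and handles edge structure", {
  design <- tiny_design(3)
  set.seed(12)
  vals <- matrix(2^stats::rnorm(60, 12, 1), nrow = 10)
  q <- make_quant(vals, design)
  p <- peptide_pca(q, design, k = 2)
  # oracle: eigenvalues of the sample covariance across samples
  x <- log2(vals); xc <- x - rowMeans(x)
  ev <- eigen(crossprod(xc), symmetric = TRUE)$values
  expect_equal(p$explained_variance_ratio, (ev / sum(ev))[1:2],
               tolerance = 1e-8)
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated samples produce identical score rows
  vals2 <- vals; vals2[, 2] <- vals2[, 1]
  p2 <- peptide_pca(make_quant(vals2, design), design)
  expect_equal(unlist(p2$scores[1, c("PC1", "PC2")]),
               unlist(p2$scores[2, c("PC1", "PC2")]), tolerance = 1e-8)
  # rank-1 structure loads entirely on PC1
  r1 <- outer(2^stats::rnorm(10), c(1, 2, 3, 4, 5, 6))
  p3 <- peptide_pca(make_quant(r1, design), design)
  expect_equal(p3$explained_variance_ratio[1], 1, tolerance = 1e-8)
  expect_error(peptide_pca(q, design, k = 10), "exceeds")
})

test_that("volcano classes respect both gates and partition the peptides", {
  d <- make_diff(paste0("p", 1:4), c("SEQA", "SEQB", "SEQC", "SEQD"),
                 "ACC1", fold_change = c(1.9, 4, 0.2, 3),
                 p_value = c(0.001, 0.5, 0.001, 0.002))
  v <- volcano_table(d)
  expect_equal(v$class, c("ns", "ns", "down", "up"))
  expect_equal(sort(unique(v$class %in% c("up", "down", "ns"))), TRUE)
  expect_equal(nrow(v), 4)
})

test_that("heatmap rows are z-scored and ordered like the reference linkage", {
  design <- tiny_design(2)
  # frozen fixture; reference average-linkage leaf order computed once with
  # an independent implementation (scipy 1.17): 4, 2, 1, 3, 5, 6
  X <- matrix(c(0.305, -1.04, 0.75, 0.941,
                -1.951, -1.302, 0.128, -0.316,
                -0.017, -0.853, 0.879, 0.778,
                0.066, 1.127, 0.468, -0.859,
                0.369, -0.959, 0.878, -0.05,
                -0.185, -0.681, 1.223, -0.155), nrow = 6, byrow = TRUE)
  q <- make_quant(2^X, design)
  h <- heatmap_table(q, design)
  expect_equal(h$peptide_id, paste0("p", c(4, 2, 1, 3, 5, 6)))
  hc <- attr(h, "hclust")
  expect_equal(hc$height,
               c(0.459439, 0.894465, 1.227147, 1.534088, 2.911106),
               tolerance = 1e-5)
  z <- as.matrix(h[design$sample_id])
  expect_equal(unname(rowMeans(z)), rep(0, 6), tolerance = 1e-8)
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 6), tolerance = 1e-8)
})

test_that("glance and tidy summarize a differential result", {
  d <- make_diff(paste0("p", 1:3), c("SEQA", "SEQB", "SEQC"), "ACC1",
                 fold_change = c(4, 0.2, 1), p_value = c(0.001, 0.001, 0.9))
  g <- glance(d)
  expect_equal(g$n_significant, 2)
  expect_equal(g$n_up, 1)
  expect_equal(g$n_down, 1)
  expect_false(inherits(tidy(d), "pep_diff"))
})
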