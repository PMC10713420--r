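scaffold <- pep_actg2_scaffold()

test_that("peptides locate at their printed precursor coordinates", {
  t2 <- dplyr::filter(pep_table2(), gene == "Actg2")
  peps <- tibble::tibble(peptide_id = t2$sequence, sequence = t2$sequence,
                         precursor_acc = scaffold$precursors$accession)
  m <- locate_peptides(peps, scaffold$precursors)
  expect_true(all(m$hit))
  expect_equal(m$start, t2$start)
  expect_equal(m$end, t2$end)
  expect_true(all(m$match_mode == "exact"))
  # round-trip: the located substring reproduces the peptide
  expect_equal(substring(scaffold$precursors$sequence, m$start, m$end),
               m$sequence)
})

test_that("missing precursors and absent peptides give no-hit, not errors", {
  peps <- tibble::tibble(
    peptide_id = c("a", "b", "c"),
    sequence = c("WWWWWWWWW", strrep("A", 500), "VITIGNERF"),
    precursor_acc = c(scaffold$precursors$accession,
                      scaffold$precursors$accession, "NOPE")
  )
  m <- locate_peptides(peps, scaffold$precursors)
  expect_equal(m$hit, c(FALSE, FALSE, FALSE))
  expect_true(all(is.na(m$start)))
})

test_that("I/L-equivalent fallback is used and flagged, never silent", {
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = "AAAILAAKVI", length = 10)
  m <- locate_peptides(tibble::tibble(sequence = "ALIAAK",
                                      precursor_acc = "T1"), prec)
  expect_true(m$hit)
  expect_equal(m$match_mode, "IL-equivalent")
  expect_equal(c(m$start, m$end), c(3, 8))
})

test_that("multi-hit peptides use the first occurrence and record all", {
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = "GGAVRKKGGAVRKK", length = 14)
  m <- locate_peptides(tibble::tibble(sequence = "GGAVR",
                                      precursor_acc = "T1"), prec)
  expect_true(m$multi_hit)
  expect_equal(m$n_hits, 2L)
  expect_equal(m$start, 1L)
  expect_equal(m$all_starts[[1]], c(1L, 8L))
})

test_that("cleavage context follows the P1/P1' convention with sentinels", {
  ctx <- cleavage_context(2, 4, "ARNDC")   # peptide RND inside ARNDC
  expect_equal(ctx$nterm_p1, "A")
  expect_equal(ctx$nterm_p1p, "R")
  expect_equal(ctx$cterm_p1, "D")
  expect_equal(ctx$cterm_p1p, "C")
  edge <- cleavage_context(1, 5, "ARNDC")
  expect_equal(edge$nterm_p1, "PROT-NTERM")
  expect_equal(edge$cterm_p1p, "PROT-CTERM")
})

test_that("domain containment distinguishes containment from mere overlap", {
  doms <- tibble::tibble(accession = "T1",
                         start = c(5L, 100L), end = c(20L, 120L),
                         name = c("DOM_A", "DOM_B"),
                         description = "", attached = TRUE)
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = strrep("A", 130), length = 130)
  maps <- tibble::tibble(
    peptide_id = c("in", "span", "out"),
    sequence = c(strrep("A", 9), strrep("A", 10), strrep("A", 5)),
    precursor_acc = "T1", hit = TRUE,
    start = c(8L, 1L, 50L), end = c(16L, 10L, 54L),
    match_mode = "exact", multi_hit = FALSE, n_hits = 1L,
    all_starts = list(8L, 1L, 50L),
    nterm_p1 = "A", nterm_p1p = "A", cterm_p1 = "A", cterm_p1p = "A"
  )
  a <- annotate_domains(maps, doms)
  expect_equal(a$domains_containing, list("DOM_A", character(0), character(0)))
  expect_equal(a$domains_overlapping, list("DOM_A", "DOM_A", character(0)))
  expect_equal(a$in_domain, c(TRUE, FALSE, FALSE))
  # containment is antitone in domain shrinkage
  shrunk <- doms; shrunk$end[1] <- 12L
  expect_false(annotate_domains(maps, shrunk)$in_domain[1])
  # every containment is also an overlap
  expect_true(all(purrr::map2_lgl(a$domains_containing,
                                  a$domains_overlapping,
                                  ~ all(.x %in% .y))))
})

test_that("all printed domain-located peptides satisfy full containment", {
  t2 <- pep_table2()
  expect_equal(nrow(t2), 34)
  expect_true(all(t2$domain_start <= t2$start & t2$end <= t2$domain_end))
  expect_equal(sum(t2$direction == "up"), 15)
  expect_equal(sum(t2$direction == "down"), 19)
})

test_that("coverage maps count per-residue overlap and conserve totals", {
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = "ARNDCEQGHI", length = 10)
  maps <- locate_peptides(
    tibble::tibble(peptide_id = c("x", "y"),
                   sequence = c("ARNDC", "DCEQG"),
                   precursor_acc = "T1"), prec)
  cov <- coverage_map(maps, prec)
  expect_equal(cov$n_all, c(1, 1, 1, 2, 2, 1, 1, 1, 0, 0))
  expect_equal(sum(cov$n_all), sum(nchar(maps$sequence)))
  # the seven candidate peptides tile disjoint intervals of the scaffold
  cand <- pep_candidates()
  m7 <- locate_peptides(
    tibble::tibble(peptide_id = cand$name, sequence = cand$sequence,
                   precursor_acc = scaffold$precursors$accession),
    scaffold$precursors)
  cov7 <- coverage_map(m7, scaffold$precursors)
  expect_equal(max(cov7$n_all), 1)
  expect_equal(sum(cov7$n_all), sum(nchar(cand$sequence)))
})

test_that("coverage splits strata by differential direction", {
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = "ARNDCEQGHI", length = 10)
  maps <- locate_peptides(
    tibble::tibble(peptide_id = c("x", "y"),
                   sequence = c("ARNDC", "DCEQG"),
                   precursor_acc = "T1"), prec)
  diff <- make_diff(c("x", "y"), c("ARNDC", "DCEQG"), "T1",
                    fold_change = c(4, 0.1), p_value = c(0.001, 0.001))
  cov <- coverage_map(maps, prec, diff)
  expect_equal(cov$n_up, c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(cov$n_down, c(0, 0, 0, 1, 1, 1, 1, 1, 0, 0))
})

test_that("cleavage profiles count positions and are order-invariant", {
  prec <- tibble::tibble(accession = "T1", gene = "",
                         sequence = "ARNDCEQGHI", length = 10)
  one <- locate_peptides(tibble::tibble(sequence = "NDCE",
                                        precursor_acc = "T1"), prec)
  prof <- cleavage_profile(one)
  expect_equal(sum(prof$n[prof$position == "Nterm-P1"]), 1)
  expect_equal(prof$residue[prof$position == "Cterm-P1" & prof$n == 1], "E")
  # sentinel positions contribute nothing
  flush <- locate_peptides(tibble::tibble(sequence = "ARNDCEQGHI",
                                          precursor_acc = "T1"), prec)
  pf <- cleavage_profile(flush)
  expect_equal(sum(pf$n[pf$position == "Nterm-P1"]), 0)
  expect_equal(sum(pf$n[pf$position == "Cterm-P1p"]), 0)
  # permutation invariance
  cand <- pep_candidates()
  peps <- tibble::tibble(peptide_id = cand$name, sequence = cand$sequence,
                         precursor_acc = scaffold$precursors$accession)
  m1 <- locate_peptides(peps, scaffold$precursors)
  m2 <- locate_peptides(peps[sample(7), ], scaffold$precursors)
  expect_equal(dplyr::arrange(cleavage_profile(m1), position, residue),
               dplyr::arrange(cleavage_profile(m2), position, residue),
               ignore_attr = TRUE)
})

test_that("precursor ranking counts distinct significant sequences", {
  t1 <- pep_table1()
  diff <- make_diff(paste0("t", seq_len(40)), t1$sequence, t1$accession,
                    fold_change = t1$fold_change, p_value = t1$p_value)
  tp <- top_precursors(diff, diff)
  expect_equal(tp$precursor_acc[1], "P63269")
  expect_equal(tp$n_peptides[1], 7L)
  expect_equal(top_precursors(tibble::tibble(precursor_acc = character(0),
                                             sequence = character(0)))$rank,
               integer(0))
  single <- top_precursors(tibble::tibble(precursor_acc = "A",
                                          sequence = "VITIGNERF"))
  expect_equal(single$rank, 1L)
})
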