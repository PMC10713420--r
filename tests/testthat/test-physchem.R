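# The seven candidate peptides and their printed descriptor values are the
# reference panel; independently computed oracle values (direct table
# summation / grid scans) back the non-printed quantities.

cand <- pep_candidates()

test_that("GRAVY reproduces the printed panel and trivial cases", {
  expect_equal(round(gravy(cand$sequence), 3), cand$gravy)
  expect_equal(gravy("V"), 4.2)
  # composition-only: invariant under reversal
  rev_seq <- vapply(strsplit(cand$sequence, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
  expect_equal(gravy(rev_seq), gravy(cand$sequence))
  expect_error(gravy(""), "empty")
})

test_that("aliphatic index reproduces the printed panel and is composition-only", {
  expect_equal(round(aliphatic_index(cand$sequence), 2), cand$aliphatic_index)
  expect_equal(aliphatic_index("GGGG"), 0)
  expect_equal(aliphatic_index("AAAA"), 100)
  set.seed(1)
  perm <- vapply(strsplit(cand$sequence, ""), function(x) {
    paste(sample(x), collapse = "")
  }, character(1))
  expect_equal(aliphatic_index(perm), aliphatic_index(cand$sequence))
})

test_that("instability index matches direct DIWV summation and splits 3/4", {
  # oracle values from direct summation over the published dipeptide table
  oracle <- c(-0.54, 45.66, 54.22, 45.17, 43.04, 10.91, 4.45)
  ii <- instability_index(cand$sequence)
  expect_equal(round(ii$instability_index, 2), oracle)
  expect_equal(sum(ii$stable), 3)
  expect_equal(sum(!ii$stable), 4)
  # all-default dipeptides (A-A weight is 1) give the closed form 10(L-1)/L
  expect_equal(instability_index("AAAA")$instability_index, 10 * 3 / 4)
  # NOT permutation-invariant: a counterexample exists
  expect_false(instability_index("AC")$instability_index ==
                 instability_index("CA")$instability_index)
  expect_error(instability_index("A"), "length")
})

test_that("half-life follows the N-end rule lookup", {
  hl <- half_life(cand$sequence)
  expect_equal(hl$half_life_h, cand$half_life_h)
  expect_equal(half_life("PGG")$half_life_h, 20)
  expect_true(half_life("PGG")$is_bound)
  expect_false(half_life("VGG")$is_bound)
  expect_equal(half_life("KGG", system = "ecoli")$half_life_h, 2 / 60)
})

test_that("monoisotopic mass is additive and reproduces labeled masses", {
  expect_equal(monoisotopic_mass("G"), 75.03202, tolerance = 1e-6)
  # auto-iTRAQ8: one label per N-terminus plus one per lysine
  expect_equal(round(monoisotopic_mass("VITIGNERF", auto_itraq8 = TRUE)), 1352)
  expect_equal(round(monoisotopic_mass("GDDLTVTNPK", auto_itraq8 = TRUE)), 1667)
  # mass additivity: concatenation loses one water
  set.seed(2)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    s1 <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 11, replace = TRUE), collapse = "")
    expect_equal(monoisotopic_mass(paste0(s1, s2)),
                 monoisotopic_mass(s1) + monoisotopic_mass(s2) - 18.01056,
                 tolerance = 1e-6)
  }
  expect_equal(
    monoisotopic_mass("VITIGNERF", modifications = list("Oxidation")),
    monoisotopic_mass("VITIGNERF") + 15.9949
  )
  expect_error(monoisotopic_mass("VITIGNERF",
                                 modifications = list("NoSuchMod")),
               "unknown modification")
  expect_equal(
    monoisotopic_mass("VITIGNERF", modifications = list("MyTag"),
                      mod_masses = c(MyTag = 100)),
    monoisotopic_mass("VITIGNERF") + 100
  )
})

test_that("net charge saturates, decreases in pH, and pI matches a grid scan", {
  # far below every pKa all basic groups (and the N-terminus) are protonated
  q0 <- net_charge("VITIGNERF", 0)      # 1 R + N-terminus
  expect_equal(q0, 2, tolerance = 1e-3)
  pH <- seq(0, 14, by = 0.5)
  q <- net_charge("GILTLKYPIEHG", pH)
  expect_true(all(diff(q) < 0))
  expect_lt(isoelectric_point("DDDD"), isoelectric_point("KKKK"))
  # grid-scan oracle: finest sign change of the same charge function
  grid <- seq(0, 14, by = 0.001)
  qg <- net_charge("VITIGNERF", grid)
  crossing <- grid[which(diff(sign(qg)) < 0)[1]]
  expect_equal(isoelectric_point("VITIGNERF"), crossing, tolerance = 0.01)
  # adding an acidic residue never raises the pI
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    s <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    expect_lte(isoelectric_point(paste0(s, "D")), isoelectric_point(s) + 1e-6)
  }
})

test_that("helical wheel angles and residue classes match the convention", {
  w <- wheel_projection("GVMVGMGQKDSYVG")
  counts <- wheel_class_counts(w)
  expect_equal(unname(counts[c("polar-basic", "polar-acidic",
                               "polar-uncharged", "nonpolar")]),
               c(1L, 1L, 2L, 10L))
  expect_equal(sum(counts), 14)
  w19 <- wheel_projection(strrep("A", 19))
  expect_equal(w19$angle_deg[1], 0)
  expect_equal(w19$angle_deg[19], 0)   # 18 * 100 = 1800 = 0 mod 360
  expect_equal(w$angle_deg[2], 100)
})

test_that("the bundled profile reproduces the printed panel deterministically", {
  prof <- physchem_profile(cand)
  expect_equal(round(prof$aliphatic_index, 2), cand$aliphatic_index)
  expect_equal(round(prof$gravy, 3), cand$gravy)
  expect_equal(prof$half_life_h, cand$half_life_h)
  expect_equal(sum(prof$stable), 3)
  # no modifications column: labeled mass equals unmodified mass
  expect_equal(prof$mass_labeled, prof$mass_mono)
  expect_identical(physchem_profile(cand), prof)
})
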