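#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues of each sequence.
#' Positive values indicate hydrophobic peptides. Bounded by the scale
#' extremes, -4.5 (all-Arg) to +4.5 (all-Ile).
#'
#' @param sequences Character vector of amino-acid sequences (standard
#'   20-letter alphabet, length >= 1 each).
#' @return Numeric vector of GRAVY values (full precision; round to 3
#'   decimals for display).
#' @examples
#' gravy("VITIGNERF") # 0.378 after rounding
#' @export
gravy <- function(sequences) {
  sequences <- validate_sequences(sequences)
  vapply(strsplit(sequences, ""), function(res) {
    mean(KD_HYDROPATHY[res])
  }, numeric(1))
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains (Ikai 1980):
#' `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with `X` the mole percent
#' of each residue. Ranges from 0 (no A/V/I/L) to 390 (poly-Ile).
#'
#' @inheritParams gravy
#' @return Numeric vector (round to 2 decimals for display).
#' @examples
#' aliphatic_index("VITIGNERF") # 118.89 after rounding
#' @export
aliphatic_index <- function(sequences) {
  sequences <- validate_sequences(sequences)
  vapply(strsplit(sequences, ""), function(res) {
    x <- table(factor(res, levels = AA_ALPHABET)) / length(res) * 100
    unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
  }, numeric(1))
}

#' Instability index
#'
#' Guruprasad (1990) dipeptide-weight statistic:
#' `II = (10 / L) * sum_i DIWV(x_i, x_{i+1})` over the L - 1 overlapping
#' dipeptides. Values below 40 predict a stable peptide/protein.
#'
#' @inheritParams gravy
#' @return A tibble with columns `sequence`, `instability_index`, `stable`.
#' @examples
#' instability_index("GVMVGMGQKDSYVG")
#' @export
instability_index <- function(sequences) {
  sequences <- validate_sequences(sequences)
  if (any(nchar(sequences) < 2L)) {
    stop("instability index needs length >= 2 (at least one dipeptide)",
         call. = FALSE)
  }
  ii <- vapply(strsplit(sequences, ""), function(res) {
    L <- length(res)
    10 / L * sum(DIWV[cbind(res[-L], res[-1])])
  }, numeric(1))
  tibble::tibble(sequence = sequences, instability_index = ii,
                 stable = ii < 40)
}

#' N-end-rule half-life
#'
#' Table lookup of the estimated in-vivo half-life from the identity of the
#' N-terminal residue (mammalian reticulocytes in vitro by default; yeast
#' and E. coli in vivo tables also available). Entries the source publishes
#' as bounds (e.g. ">20 h" for Pro in the mammalian system) are returned as
#' the bound's value with `is_bound = TRUE`.
#'
#' @inheritParams gravy
#' @param system One of `"mammalian"`, `"yeast"`, `"ecoli"`.
#' @return A tibble with columns `sequence`, `nterm_residue`, `half_life_h`,
#'   `is_bound`.
#' @examples
#' half_life(c("VITIGNERF", "QPSFIGMESAGIHETTY")) # 100 h, 0.8 h
#' @export
half_life <- function(sequences, system = c("mammalian", "yeast", "ecoli")) {
  system <- match.arg(system)
  sequences <- validate_sequences(sequences)
  nt <- substr(sequences, 1L, 1L)
  bounds <- HALF_LIFE_IS_BOUND[[system]]
  tibble::tibble(
    sequence = sequences,
    nterm_residue = nt,
    half_life_h = unname(HALF_LIFE_H[[system]][nt]),
    is_bound = !is.na(bounds[nt]) & unname(bounds[nt])
  )
}

#' Monoisotopic peptide mass, with optional modifications
#'
#' Sum of monoisotopic residue masses plus one water (18.01056 Da), plus the
#' masses of any modifications. Three modification names carry built-in
#' monoisotopic masses: `iTRAQ8` (+304.2054 per label), `Oxidation`
#' (+15.9949), `Acetyl` (+42.0106); others must be supplied via `mod_masses`.
#'
#' With `auto_itraq8 = TRUE` the 8-plex labeling convention is applied
#' instead of an explicit modification list: one label per free N-terminus
#' plus one per lysine, the standard amine-reactive chemistry.
#'
#' @inheritParams gravy
#' @param modifications Either `NULL`, or a list (one element per sequence)
#'   of character vectors of modification names; positions are irrelevant to
#'   the mass sum.
#' @param auto_itraq8 Logical; apply one iTRAQ8 label per N-terminus and per
#'   lysine, ignoring `modifications`.
#' @param mod_masses Named numeric vector extending/overriding the built-in
#'   modification mass map.
#' @return Numeric vector of masses in Da (full precision).
#' @examples
#' monoisotopic_mass("VITIGNERF", auto_itraq8 = TRUE) # 1351.78 -> prints 1352
#' @export
monoisotopic_mass <- function(sequences, modifications = NULL,
                              auto_itraq8 = FALSE, mod_masses = NULL) {
  sequences <- validate_sequences(sequences)
  mass_map <- MOD_MASS
  if (!is.null(mod_masses)) mass_map[names(mod_masses)] <- mod_masses
  base <- vapply(strsplit(sequences, ""), function(res) {
    sum(MONO_MASS[res]) + MASS_WATER
  }, numeric(1))
  if (auto_itraq8) {
    n_labels <- 1L + stringr::str_count(sequences, stringr::fixed("K"))
    return(base + n_labels * mass_map[["iTRAQ8"]])
  }
  if (is.null(modifications)) return(base)
  stopifnot(length(modifications) == length(sequences))
  extra <- vapply(modifications, function(mods) {
    if (length(mods) == 0L) return(0)
    unknown <- setdiff(mods, names(mass_map))
    if (length(unknown)) {
      stop("unknown modification(s) with no supplied mass: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    sum(mass_map[mods])
  }, numeric(1))
  base + extra
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups with the Bjellqvist pKa
#' set: positive groups are the alpha-amino terminus (residue-dependent pKa)
#' and K/R/H side chains; negative groups are the carboxy terminus and
#' D/E/C/Y side chains. Strictly decreasing in pH.
#'
#' @param sequence A single sequence.
#' @param pH Numeric vector of pH values.
#' @return Net charge at each pH.
#' @export
net_charge <- function(sequence, pH) {
  sequence <- validate_sequences(sequence)
  stopifnot(length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  nt <- res[1]
  pka_nterm <- if (nt %in% names(PKA_NTERM_BY_RES)) {
    PKA_NTERM_BY_RES[[nt]]
  } else {
    PKA_NTERM_DEFAULT
  }
  counts <- table(factor(res, levels = AA_ALPHABET))
  pos_pka <- c(pka_nterm, rep(PKA_SIDE_POS, counts[names(PKA_SIDE_POS)]))
  neg_pka <- c(PKA_CTERM, rep(PKA_SIDE_NEG, counts[names(PKA_SIDE_NEG)]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH of zero net charge, found by bisection on \[0, 14\] of the
#' [net_charge()] function (Bjellqvist pKa set) to |charge| < `tol`.
#'
#' @inheritParams gravy
#' @param tol Convergence tolerance on the absolute net charge.
#' @return Numeric vector of pI values (pH units).
#' @examples
#' isoelectric_point("VITIGNERF")
#' @export
isoelectric_point <- function(sequences, tol = 1e-4) {
  sequences <- validate_sequences(sequences)
  vapply(sequences, function(s) {
    lo <- 0; hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid)
      if (abs(q) < tol || hi - lo < 1e-8) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Helical-wheel projection
#'
#' Places residue i at angle `(i - 1) * step_deg mod 360` on an idealized
#' alpha-helical wheel (100 degrees per residue, 3.6 residues/turn) and
#' classifies each residue as nonpolar, polar-uncharged, polar-basic or
#' polar-acidic. Aromatics (F, W, Y) are classed nonpolar.
#'
#' @param sequence A single sequence.
#' @param step_deg Rotation per residue in degrees.
#' @return A tibble (class `pep_wheel`) with columns `index`, `residue`,
#'   `angle_deg`, `residue_class`; class counts are available via
#'   [wheel_class_counts()] or `summary()`.
#' @examples
#' wheel_projection("GVMVGMGQKDSYVG")
#' @export
wheel_projection <- function(sequence, step_deg = 100) {
  sequence <- validate_sequences(sequence)
  stopifnot(length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  out <- tibble::tibble(
    index = seq_along(res),
    residue = res,
    angle_deg = ((seq_along(res) - 1) * step_deg) %% 360,
    residue_class = factor(unname(RESIDUE_CLASS[res]),
                           levels = RESIDUE_CLASS_LEVELS)
  )
  class(out) <- c("pep_wheel", class(out))
  attr(out, "sequence") <- sequence
  out
}

#' Residue-class counts of a helical-wheel projection
#'
#' @param wheel A [wheel_projection()] result.
#' @return A named integer vector over the four polarity classes.
#' @export
wheel_class_counts <- function(wheel) {
  stopifnot(inherits(wheel, "pep_wheel"))
  tab <- table(wheel$residue_class)
  stats::setNames(as.integer(tab), names(tab))
}

#' Full physicochemical descriptor panel
#'
#' Bundles length, monoisotopic mass (unmodified and with the record's
#' modifications applied), GRAVY, aliphatic index, instability index and
#' stability call, N-end-rule half-life, and isoelectric point into one row
#' per peptide. This is the ProtParam-style characterization panel.
#'
#' @param peptides A data frame with at least a `sequence` column; optional
#'   `peptide_id` and `modifications` (list-column of tibbles with a `name`
#'   column, as produced by [read_quant_table()]).
#' @param auto_itraq8 Logical; if `TRUE`, `mass_labeled` uses the iTRAQ
#'   8-plex convention (one label per N-terminus and per lysine) instead of
#'   the record's modification list.
#' @param half_life_system Passed to [half_life()].
#' @return A tibble, one row per input row: `peptide_id`, `sequence`,
#'   `length`, `mass_mono`, `mass_labeled`, `gravy`, `aliphatic_index`,
#'   `instability_index`, `stable`, `half_life_h`, `half_life_is_bound`,
#'   `pI`.
#' @examples
#' physchem_profile(pep_candidates())
#' @export
physchem_profile <- function(peptides, auto_itraq8 = FALSE,
                             half_life_system = "mammalian") {
  peptides <- tibble::as_tibble(peptides)
  stopifnot("sequence" %in% names(peptides))
  seqs <- validate_sequences(peptides$sequence)
  ids <- if ("peptide_id" %in% names(peptides)) {
    as.character(peptides$peptide_id)
  } else {
    seqs
  }
  mods <- if ("modifications" %in% names(peptides) && !auto_itraq8) {
    purrr::map(peptides$modifications, function(m) {
      if (is.null(m) || (is.data.frame(m) && nrow(m) == 0L)) character(0)
      else if (is.data.frame(m)) as.character(m$name)
      else as.character(m)
    })
  } else {
    NULL
  }
  ii <- instability_index(seqs)
  hl <- half_life(seqs, system = half_life_system)
  tibble::tibble(
    peptide_id = ids,
    sequence = seqs,
    length = nchar(seqs),
    mass_mono = monoisotopic_mass(seqs),
    mass_labeled = monoisotopic_mass(seqs, modifications = mods,
                                     auto_itraq8 = auto_itraq8),
    gravy = gravy(seqs),
    aliphatic_index = aliphatic_index(seqs),
    instability_index = ii$instability_index,
    stable = ii$stable,
    half_life_h = hl$half_life_h,
    half_life_is_bound = hl$is_bound,
    pI = isoelectric_point(seqs)
  )
}
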