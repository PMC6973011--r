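# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical-form equality through the package's normalizer
canon_eq <- function(a, b) {
  identical(normalize_compound(a), normalize_compound(b))
}

# Independent average-MW oracle: hand sums of standard atomic weights
# (CIAAW 2021 abridged values), implicit hydrogens included.
hand_mw_table <- function() {
  data.frame(
    smiles = c("O", "C", "CCO", "c1ccccc1", "Oc1ccccc1", "CC(=O)O",
               "c1ccc2ccccc2c1", "Oc1ccc(O)cc1", "CN", "ClCc1ccccc1",
               "O=P(O)(O)Oc1ccccc1", "CCCCCCCC", "CC(C)O", "c1ccncc1",
               "CS"),
    mw = c(
      2 * 1.008 + 15.999,                       # water
      12.011 + 4 * 1.008,                       # methane
      2 * 12.011 + 6 * 1.008 + 15.999,          # ethanol
      6 * 12.011 + 6 * 1.008,                   # benzene
      6 * 12.011 + 6 * 1.008 + 15.999,          # phenol
      2 * 12.011 + 4 * 1.008 + 2 * 15.999,      # acetic acid
      10 * 12.011 + 8 * 1.008,                  # naphthalene
      6 * 12.011 + 6 * 1.008 + 2 * 15.999,      # hydroquinone
      12.011 + 5 * 1.008 + 14.007,              # methylamine
      7 * 12.011 + 7 * 1.008 + 35.45,           # benzyl chloride
      6 * 12.011 + 7 * 1.008 + 4 * 15.999 + 30.974,  # phenyl phosphate
      8 * 12.011 + 18 * 1.008,                  # octane
      3 * 12.011 + 8 * 1.008 + 15.999,          # isopropanol
      5 * 12.011 + 5 * 1.008 + 14.007,          # pyridine
      12.011 + 4 * 1.008 + 32.06                # methanethiol
    ),
    stringsAsFactors = FALSE
  )
}

# Monoisotopic mass of the HPO3 group added per phosphorylation:
# 1H + 31P + 3 * 16O from the standard isotope masses.
HPO3_MONO <- 1.0078250319 + 30.97376151 + 3 * 15.9949146221

# A pool of distinct phenolic molecules built from the planted-composition
# generator (class phenolic_pass only).
phenolic_pool <- function(n, seed = 99L) {
  spec <- library_spec(n_total = n, n_phenolic_pass = n, n_over_mw = 0L,
                       n_reactive = 0L, n_nonphenolic = 0L, n_acyclic = 0L,
                       seed = seed)
  generate_library(spec)$truth$smiles
}

# A small multi-model PDBQT text fixture with two scored models.
two_model_pdbqt <- function(path, scores = c(-7.1, -6.4)) {
  lines <- unlist(lapply(seq_along(scores), function(i) {
    c(sprintf("MODEL %d", i),
      sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000", scores[i]),
      "ATOM      1  P1  LIG A   1       1.000   2.000   3.000  1.00  0.00     0.000 P ",
      sprintf("ATOM      2  O1  LIG A   1       1.000   2.000   %5.3f  1.00  0.00     0.000 O ", 4.5 + i),
      "ENDMDL")
  }))
  writeLines(lines, path)
  path
}

# Minimal receptor PDB with an altloc pair on one atom.
altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  NZ ALYS A 591       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  NZ BLYS A 591       1.000   0.000   0.000  0.40  0.00           N",
    "ATOM      3  CA  LYS A 591       2.000   1.000   0.000  1.00  0.00           C",
    "ATOM      4  NH1 ARG A 609       4.000   0.000   0.000  1.00  0.00           N",
    "END"), path)
  path
}
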