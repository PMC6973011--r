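# Synthetic fixtures with planted ground truth: compound libraries of
# controlled composition, and toy receptor/pose sets with prescribed
# phosphate-residue geometry. Class membership is provable by construction:
# every class is built from templated SMILES; the seed only shuffles
# decorations and record order.

#' Specification of a planted-composition compound library
#'
#' Five classes of members, each designed to reach a specific fate under
#' [apply_fragment_filters()] with the default [filter_config()]:
#' `phenolic_pass` (scaffold-matching phenolic fragments, MW < 500, no
#' reactive group), `over_mw` (phenolic but MW >= 500), `reactive` (phenolic,
#' in-weight, but carrying a default-set electrophile), `nonphenolic`
#' (scaffold-matching, no phenolic hydroxyl), `acyclic` (no ring at all).
#'
#' @param n_total Total records; must equal the sum of the class counts.
#' @param n_phenolic_pass,n_over_mw,n_reactive,n_nonphenolic,n_acyclic
#'   Class counts.
#' @param seed Integer seed controlling decoration choice and record order.
#' @return A `library_spec`.
#' @export
library_spec <- function(n_total = 1000L, n_phenolic_pass = 300L,
                         n_over_mw = 200L, n_reactive = 150L,
                         n_nonphenolic = 250L, n_acyclic = 100L,
                         seed = 1L) {
  counts <- c(phenolic_pass = n_phenolic_pass, over_mw = n_over_mw,
              reactive = n_reactive, nonphenolic = n_nonphenolic,
              acyclic = n_acyclic)
  if (sum(counts) != n_total) {
    ps_stop(sprintf("class counts sum to %d, not n_total = %d",
                    sum(counts), n_total), "ps_error_invalid")
  }
  structure(list(n_total = as.integer(n_total), counts = as.integer(counts),
                 classes = names(counts), seed = as.integer(seed)),
            class = "library_spec")
}

# Decorated hydroxy-aryl cores whose framework is (or prunes to) a default
# scaffold-set entry. %s slots take benign alkyl/alkoxy decorations.
#' @noRd
fixture_templates <- function() {
  list(
    phenolic_core = c(
      "Oc1ccc(%s)cc1",            # phenol        -> benzene
      "Oc1cc(%s)ccc1%s",          # phenol, 2 slots
      "Oc1ccc(-c2ccc(%s)cc2)cc1", # 4-phenylphenol-> biphenyl
      "Oc1ccc2ccccc2c1",          # naphthol      -> naphthalene
      "Oc1ccc2cc(%s)ccc2c1",      # naphthol
      "Oc1ccc2[nH]ccc2c1",        # hydroxyindole -> indole
      "Oc1ccc2ncccc2c1",          # hydroxyquinoline -> quinoline
      "O=C1C=C(c2ccc(O)cc2)Oc2ccccc21"  # hydroxyflavone -> flavone
    ),
    decoration = c("C", "CC", "CCC", "CCCC", "C(C)C", "OC", "OCC", "CO",
                   "CCO", "N(C)C", "CN", "F"),
    long_chain = vapply(30:40, function(n) paste(rep("C", n), collapse = ""), ""),
    reactive_tag = c("C=CC(C)=O",  # Michael acceptor
                     "C=O",        # aldehyde
                     "CCl",        # alkyl/benzyl halide
                     "CC2CO2",     # epoxide (ring label 2: templates use 1)
                     "C(=O)Cl",    # acyl halide
                     "CN=C=O"),    # isocyanate
    nonphenolic = c(
      "COc1ccc(%s)cc1",           # anisoles -> benzene
      "Cc1ccc(%s)cc1",            # toluenes
      "CCc1ccc2ccccc2c1",         # alkyl naphthalene
      "COc1ccc2ncccc2c1",         # methoxyquinoline
      "Cc1ccc(-c2ccccc2)cc1"      # methylbiphenyl
    ),
    acyclic = c("CCO", "CCCC", "CCOCC", "CC(C)O", "CCN", "CCCCO",
                "CCOC(C)C", "CC(C)CC", "OCCO", "CCCOC")
  )
}

#' @noRd
fill_slots <- function(template, decorations) {
  nslot <- lengths(regmatches(template, gregexpr("%s", template, fixed = TRUE)))
  args <- as.list(sample(decorations, nslot, replace = TRUE))
  do.call(sprintf, c(list(template), args))
}

#' Generate a compound library with planted composition
#'
#' Deterministic for a fixed seed: two runs with the same spec produce
#' byte-identical files. The ground truth lists each id's intended class and
#' the filter stage it is designed to fail (or `"pass"`).
#'
#' @param spec A [library_spec()].
#' @param smi_path Output `.smi` path.
#' @param truth_path Output ground-truth TSV path (columns: id, class,
#'   expected_fate).
#' @return Invisibly, a list with `smi_path`, `truth_path`, and the truth
#'   data.frame.
#' @export
generate_library <- function(spec, smi_path = tempfile(fileext = ".smi"),
                             truth_path = tempfile(fileext = ".tsv")) {
  ps_assert(inherits(spec, "library_spec"), "spec must be a library_spec")
  tpl <- fixture_templates()
  fate <- c(phenolic_pass = "pass", over_mw = "mw", reactive = "reactive",
            nonphenolic = "phenol", acyclic = "scaffold")
  with_seed(spec$seed, {
    smiles <- character(0)
    class <- character(0)
    for (k in seq_along(spec$classes)) {
      cl <- spec$classes[k]
      n <- spec$counts[k]
      if (n == 0L) next
      smi <- switch(cl,
        phenolic_pass = vapply(sample(tpl$phenolic_core, n, replace = TRUE),
                               fill_slots, "", decorations = tpl$decoration,
                               USE.NAMES = FALSE),
        over_mw = sprintf("Oc1ccc(%s)cc1",
                          sample(tpl$long_chain, n, replace = TRUE)),
        reactive = sprintf("Oc1ccc(%s)cc1",
                           sample(tpl$reactive_tag, n, replace = TRUE)),
        nonphenolic = vapply(sample(tpl$nonphenolic, n, replace = TRUE),
                             fill_slots, "", decorations = tpl$decoration,
                             USE.NAMES = FALSE),
        acyclic = sample(tpl$acyclic, n, replace = TRUE))
      smiles <- c(smiles, smi)
      class <- c(class, rep(cl, n))
    }
    ord <- sample.int(length(smiles))
    smiles <- smiles[ord]
    class <- class[ord]
  })
  ids <- sprintf("cpd%06d", seq_along(smiles))
  writeLines(paste(smiles, ids), smi_path)
  truth <- data.frame(id = ids, smiles = smiles, class = class,
                      expected_fate = unname(fate[class]),
                      stringsAsFactors = FALSE)
  write_tsv(truth, truth_path)
  invisible(list(smi_path = smi_path, truth_path = truth_path, truth = truth))
}

#' Specification of a toy receptor / pose-set fixture
#'
#' @param n_ligands Number of ligands; `n_pass_geometry` of them have their
#'   phosphate planted at `pass_distance` from every target atom set, the
#'   rest at `fail_distance` (must be strictly larger).
#' @param target_specs List of [residue_atom_spec()]; default Arg609
#'   (NH1/NH2/NE) and Lys591 (NZ) on chain A.
#' @param pass_distance,fail_distance Planted minimum distances in Angstrom.
#' @param n_poses Poses per ligand (pose 1 carries the planted geometry;
#'   further poses are shifted away).
#' @param seed Integer seed (shuffles ligand order only).
#' @return A `pose_fixture_spec`.
#' @export
pose_fixture_spec <- function(n_ligands = 10L, n_pass_geometry = 4L,
                              target_specs = NULL,
                              pass_distance = 3.0, fail_distance = 8.0,
                              n_poses = 3L, seed = 1L) {
  target_specs <- target_specs %||% list(
    residue_atom_spec("A", "ARG", 609, c("NH1", "NH2", "NE")),
    residue_atom_spec("A", "LYS", 591, "NZ"))
  ps_assert(n_pass_geometry <= n_ligands, "n_pass_geometry must be <= n_ligands")
  if (!(fail_distance > pass_distance)) {
    ps_stop("fail_distance must be strictly greater than pass_distance",
            "ps_error_invalid")
  }
  structure(list(n_ligands = as.integer(n_ligands),
                 n_pass_geometry = as.integer(n_pass_geometry),
                 target_specs = target_specs,
                 pass_distance = pass_distance, fail_distance = fail_distance,
                 n_poses = as.integer(n_poses), seed = as.integer(seed)),
            class = "pose_fixture_spec")
}

#' @noRd
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, element) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, chain, resno, xyz[1], xyz[2], xyz[3], element)
}

# Toy receptor: the two target residues reduced to the side-chain atoms the
# criteria address, plus a backbone stub each. Non-physical by design — the
# distance logic needs coordinates and residue addressing, not a protein.
#' @noRd
toy_receptor_atoms <- function() {
  list(
    list(name = "CA",  resname = "LYS", resno = 591L, xyz = c(-2.0, -6.0, 0.0), element = "C"),
    list(name = "CE",  resname = "LYS", resno = 591L, xyz = c(-1.0, -4.0, 0.0), element = "C"),
    list(name = "NZ",  resname = "LYS", resno = 591L, xyz = c(0.0, 0.0, 0.0),   element = "N"),
    list(name = "CA",  resname = "ARG", resno = 609L, xyz = c(6.0, -6.0, 0.0),  element = "C"),
    list(name = "CZ",  resname = "ARG", resno = 609L, xyz = c(4.0, -1.2, 0.0),  element = "C"),
    list(name = "NE",  resname = "ARG", resno = 609L, xyz = c(4.0, -2.5, 0.0),  element = "N"),
    list(name = "NH1", resname = "ARG", resno = 609L, xyz = c(4.0, 0.0, 0.0),   element = "N"),
    list(name = "NH2", resname = "ARG", resno = 609L, xyz = c(5.2, -1.8, 0.0),  element = "N")
  )
}

#' Generate a toy receptor and pose files with planted geometry
#'
#' The receptor places Lys591 NZ at the origin and Arg609 NH1 at (4, 0, 0) on
#' chain A (other addressed atoms further away). Its documented docking box —
#' search boxes have no package defaults — is center (2, 2, 0), size
#' 20 Angstrom per axis, which covers both target residues and every planted
#' pose. Each passing ligand's
#' nearest phosphate atom sits on the perpendicular bisector plane of those
#' two nitrogens at exactly the planted distance from both; failing ligands
#' use the same construction at `fail_distance`. Pose 1 carries the planted
#' geometry; later poses are shifted away in +y. Scores are deterministic and
#' non-decreasing within each pose set.
#'
#' @param spec A [pose_fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `receptor_path`, `pose_paths` (named by
#'   ligand id), `truth_path`, and the truth data.frame (columns: ligand_id,
#'   passes, planted_distance).
#' @export
generate_receptor_and_poses <- function(spec, dir = tempfile("posefix")) {
  ps_assert(inherits(spec, "pose_fixture_spec"), "spec must be a pose_fixture_spec")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  receptor_path <- file.path(dir, "toy_receptor.pdb")
  atoms <- toy_receptor_atoms()
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    pdb_atom_line(i, a$name, a$resname, "A", a$resno, a$xyz, a$element)
  }, "")
  writeLines(c("REMARK synthetic toy receptor (phosphoscreen fixture)",
               lines, "END"), receptor_path)

  n <- spec$n_ligands
  passes <- c(rep(TRUE, spec$n_pass_geometry), rep(FALSE, n - spec$n_pass_geometry))
  passes <- with_seed(spec$seed, sample(passes))
  ids <- sprintf("lig%03d", seq_len(n))

  # anchor point at distance D from both NZ (0,0,0) and NH1 (4,0,0):
  # (2, sqrt(D^2 - 4), 0); remaining phosphate atoms stacked further in +y.
  pose_paths <- character(0)
  for (i in seq_len(n)) {
    D <- if (passes[i]) spec$pass_distance else spec$fail_distance
    y0 <- round(sqrt(D^2 - 4), 3L)
    anchor <- c(2, y0, 0)
    lig_atoms <- rbind(
      O1 = anchor,
      P1 = anchor + c(0, 1.6, 0),
      O2 = anchor + c(0, 1.6, 1.6),
      O3 = anchor + c(0, 1.6, -1.6),
      O4 = anchor + c(0, 3.2, 0),
      C1 = anchor + c(0, 4.8, 0),
      C2 = anchor + c(0, 6.2, 0)
    )
    el <- substring(rownames(lig_atoms), 1L, 1L)
    models <- lapply(seq_len(spec$n_poses), function(p) {
      shift <- c(0, 3.0 * (p - 1L), 0)
      xyz <- sweep(lig_atoms, 2L, shift, `+`)
      list(pose_index = p,
           score = round(-9 + 0.2 * i + 0.1 * (p - 1L), 3L),
           atoms = data.frame(serial = seq_len(nrow(xyz)),
                              name = rownames(lig_atoms), element = el,
                              x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                              stringsAsFactors = FALSE))
    })
    path <- file.path(dir, paste0(ids[i], ".pdbqt"))
    write_pose_file(structure(list(ligand_id = ids[i], models = models,
                                   source_path = path), class = "pose_set"),
                    path)
    pose_paths[ids[i]] <- path
  }
  truth <- data.frame(ligand_id = ids, passes = passes,
                      planted_distance = ifelse(passes, spec$pass_distance,
                                                spec$fail_distance),
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write_tsv(truth, truth_path)
  invisible(list(receptor_path = receptor_path, pose_paths = pose_paths,
                 truth_path = truth_path, truth = truth))
}
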