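test_that("library generation is byte-deterministic for a fixed seed", {
  spec <- library_spec(100, 30, 20, 15, 20, 15, seed = 42)
  a <- generate_library(spec, tempfile(fileext = ".smi"), tempfile(fileext = ".tsv"))
  b <- generate_library(spec, tempfile(fileext = ".smi"), tempfile(fileext = ".tsv"))
  expect_identical(readLines(a$smi_path), readLines(b$smi_path))
  expect_identical(readLines(a$truth_path), readLines(b$truth_path))
  # a different seed shuffles composition
  c_ <- generate_library(library_spec(100, 30, 20, 15, 20, 15, seed = 43))
  expect_false(identical(readLines(a$smi_path), readLines(c_$smi_path)))
})

test_that("library generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_library(library_spec(20, 6, 4, 3, 5, 2, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("inconsistent class counts are fatal", {
  expect_error(library_spec(100, 10, 10, 10, 10, 10), class = "ps_error_invalid")
})

test_that("planted classes are class-consistent under independent checks", {
  g <- generate_library(library_spec(150, 50, 25, 25, 30, 20, seed = 17))
  tr <- g$truth
  expect_true(all(!is.na(normalize_compound(tr$smiles))))
  nph <- count_phenolic_hydroxyls(tr$smiles)
  expect_true(all(nph[tr$class %in% c("phenolic_pass", "over_mw", "reactive")] >= 1L))
  expect_true(all(nph[tr$class == "nonphenolic"] == 0L))
  mw <- molecular_weight(tr$smiles)
  expect_true(all(mw[tr$class == "phenolic_pass"] < 500))
  expect_true(all(mw[tr$class == "over_mw"] >= 500))
  acyclic <- vapply(tr$smiles[tr$class == "acyclic"],
                    function(s) is.na(extract_ring_scaffold(s)), TRUE,
                    USE.NAMES = FALSE)
  expect_true(all(acyclic))
  expect_true(all(has_reactive_moiety(tr$smiles[tr$class == "reactive"])$reactive))
  expect_true(all(!has_reactive_moiety(tr$smiles[tr$class == "phenolic_pass"])$reactive))
})

test_that("pose fixtures validate their geometry specification", {
  expect_error(pose_fixture_spec(10, 4, pass_distance = 5, fail_distance = 5),
               class = "ps_error_invalid")
  expect_error(pose_fixture_spec(4, 10), class = "phosphoscreen_error")
})

test_that("pose fixture generation is deterministic and self-consistent", {
  spec <- pose_fixture_spec(6, 2, seed = 9)
  a <- generate_receptor_and_poses(spec, dir = tempfile())
  b <- generate_receptor_and_poses(spec, dir = tempfile())
  expect_identical(readLines(a$receptor_path), readLines(b$receptor_path))
  for (id in names(a$pose_paths)) {
    expect_identical(readLines(a$pose_paths[[id]]), readLines(b$pose_paths[[id]]))
  }
  # planted distances read back through the production readers
  rec <- parse_receptor(a$receptor_path)
  nz <- as.matrix(rec[rec$atom_name == "NZ", c("x", "y", "z")])
  for (i in seq_len(nrow(a$truth))) {
    ps <- parse_pose_file(a$pose_paths[[a$truth$ligand_id[i]]])
    grp <- locate_phosphate_atoms(ps$models[[1]]$atoms)
    rows <- unique(c(grp[[1]]$p_row, grp[[1]]$o_rows))
    d <- min_distance(as.matrix(ps$models[[1]]$atoms[rows, c("x", "y", "z")]), nz)
    expect_equal(d, a$truth$planted_distance[i], tolerance = 0.001)
  }
})
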