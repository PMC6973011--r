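test_that("toy receptors parse with exact coordinates and addressing", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(2, 1, seed = 2))
  rec <- parse_receptor(fx$receptor_path)
  expect_s3_class(rec, "receptor_structure")
  nz <- rec[rec$residue_number == 591 & rec$atom_name == "NZ", ]
  expect_equal(unlist(nz[, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0))
  expect_true(all(c("NH1", "NH2", "NE") %in%
                    rec$atom_name[rec$residue_number == 609]))
  expect_equal(unique(rec$chain_id), "A")
})

test_that("altloc resolution keeps the highest occupancy", {
  f <- altloc_pdb(tempfile(fileext = ".pdb"))
  rec <- parse_receptor(f)
  nz <- rec[rec$atom_name == "NZ", ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$x, 0)  # altloc A, occupancy 0.60
})

test_that("unresolvable residue requests are typed configuration errors", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(2, 1, seed = 2))
  rec <- parse_receptor(fx$receptor_path)
  poses <- lapply(names(fx$pose_paths),
                  function(id) parse_pose_file(fx$pose_paths[[id]], id))
  bad <- list(Z = distance_criterion(
    residue_atom_spec("Z", "ARG", 609, "NH1"), 4.0))
  expect_error(apply_distance_criteria(poses, rec, bad),
               class = "ps_error_residue_not_found")
})

test_that("phosphate location finds P plus covalent oxygens", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(1, 1, seed = 3))
  ps <- parse_pose_file(fx$pose_paths[[1]])
  grp <- locate_phosphate_atoms(ps$models[[1]]$atoms)
  expect_length(grp, 1L)
  expect_length(grp[[1]]$o_rows, 4L)
  # unphosphorylated model errors
  noP <- data.frame(element = c("C", "O"), x = 0:1, y = 0, z = 0)
  expect_error(locate_phosphate_atoms(noP), class = "ps_error_no_phosphate")
  # two independent phosphates are both reported
  twoP <- data.frame(element = c("P", "O", "P", "O"),
                     x = c(0, 1.6, 10, 11.6), y = 0, z = 0)
  expect_length(locate_phosphate_atoms(twoP), 2L)
})

test_that("min_distance matches hand values and a brute-force oracle", {
  expect_equal(min_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  expect_equal(min_distance(rbind(c(1, 2, 3)), rbind(c(1, 2, 3))), 0)
  expect_error(min_distance(matrix(numeric(0), 0, 3), rbind(c(0, 0, 0))),
               class = "phosphoscreen_error")
  brute <- function(a, b) {
    best <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
    best
  }
  for (s in 1:100) {
    set.seed(s)
    a <- matrix(runif(60, -10, 10), ncol = 3)
    b <- matrix(runif(45, -10, 10), ncol = 3)
    expect_identical(min_distance(a, b), brute(a, b))
  }
})

test_that("distance triage recovers the planted pass set exactly", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(10, 4, seed = 5))
  rec <- parse_receptor(fx$receptor_path)
  poses <- lapply(names(fx$pose_paths),
                  function(id) parse_pose_file(fx$pose_paths[[id]], id))
  res <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0))
  expect_setequal(res$passed_ids, fx$truth$ligand_id[fx$truth$passes])
  fun <- as.data.frame(res$funnel)
  expect_equal(fun$n_in, 10L)
  expect_equal(fun$n_out, 4L)
  h <- res$hits[res$hits$passed, ]
  expect_true(all(abs(h$d_ARG609 - 3.0) < 0.001))
  expect_true(all(abs(h$d_LYS591 - 3.0) < 0.001))
})

test_that("triage is invariant to pose-set input order and threshold-monotone", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(12, 5, seed = 6))
  rec <- parse_receptor(fx$receptor_path)
  poses <- lapply(names(fx$pose_paths),
                  function(id) parse_pose_file(fx$pose_paths[[id]], id))
  fwd <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0))
  rev <- apply_distance_criteria(rev(poses), rec, default_distance_criteria(4.0))
  expect_setequal(fwd$passed_ids, rev$passed_ids)
  sweep <- vapply(seq(2, 10, by = 0.5), function(thr) {
    length(apply_distance_criteria(poses, rec,
                                   default_distance_criteria(thr))$passed_ids)
  }, 1L)
  expect_true(all(diff(sweep) >= 0))  # loosening never shrinks the pass set
  # very large ceiling passes every phosphorylated ligand
  all_pass <- apply_distance_criteria(poses, rec, default_distance_criteria(1e6))
  expect_length(all_pass$passed_ids, 12L)
})

test_that("ligands without phosphorus fail with a reason, never crash", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(2, 1, seed = 7))
  rec <- parse_receptor(fx$receptor_path)
  f <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:      -5.000      0.000      0.000",
    "ATOM      1  C1  LIG A   1       2.000   2.236   0.000  1.00  0.00     0.000 C ",
    "ENDMDL"), f)
  poses <- c(lapply(names(fx$pose_paths),
                    function(id) parse_pose_file(fx$pose_paths[[id]], id)),
             list(parse_pose_file(f, "noP")))
  res <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0))
  row <- res$hits[res$hits$ligand_id == "noP", ]
  expect_false(row$passed)
  expect_match(row$reason, "phosphorylated")
  expect_false("noP" %in% res$passed_ids)
})

test_that("any-pose policy rescues ligands whose later pose satisfies criteria", {
  fx <- generate_receptor_and_poses(pose_fixture_spec(2, 1, seed = 8))
  rec <- parse_receptor(fx$receptor_path)
  # hand-built ligand: pose 1 sits far from the pocket, pose 2 in contact
  atom <- function(serial, name, el, x, y, z) sprintf(
    "ATOM  %5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00     0.000 %-2s",
    serial, name, x, y, z, el)
  far <- c(2, 7.746, 0); near <- c(2, 2.236, 0)
  f <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1", "REMARK VINA RESULT:      -6.000      0.000      0.000",
    atom(1, "O1", "O", far[1], far[2], far[3]),
    atom(2, "P1", "P", far[1], far[2] + 1.6, far[3]),
    "ENDMDL",
    "MODEL 2", "REMARK VINA RESULT:      -5.500      0.000      0.000",
    atom(1, "O1", "O", near[1], near[2], near[3]),
    atom(2, "P1", "P", near[1], near[2] + 1.6, near[3]),
    "ENDMDL"), f)
  poses <- list(parse_pose_file(f, "late_binder"))
  best <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0),
                                  pose_policy = "best-pose-only")
  any_ <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0),
                                  pose_policy = "any-pose")
  expect_length(best$passed_ids, 0L)
  expect_equal(any_$passed_ids, "late_binder")
  # the first passing pose is the one recorded as passed
  passed_rows <- any_$hits[any_$hits$passed, ]
  expect_equal(passed_rows$pose_index, 2L)
  # best-pose-only evaluates exactly one record per ligand
  expect_equal(nrow(best$hits), 1L)
  expect_true(all(best$hits$pose_index == 1L))
})

test_that("ranking sorts by score, then distance sum, then id, and is stable", {
  h <- data.frame(
    ligand_id = c("c", "a", "b", "d"),
    pose_index = 1L,
    score = c(-7.2, -9.1, -8.0, -8.0),
    d_ARG609 = c(3.0, 3.0, 2.0, 1.0),
    d_LYS591 = c(3.0, 3.0, 3.1, 3.2),
    passed = c(TRUE, TRUE, TRUE, TRUE),
    reason = "",
    stringsAsFactors = FALSE)
  r <- rank_hits(h)
  expect_equal(r$ligand_id, c("a", "d", "b", "c"))  # 4.2 < 5.1 tie-break at -8.0
  expect_equal(r$rank, 1:4)
  h$passed <- FALSE
  expect_equal(nrow(rank_hits(h)), 0L)
})
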