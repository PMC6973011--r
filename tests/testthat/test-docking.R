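make_dock_fixture <- function() {
  fx <- generate_receptor_and_poses(pose_fixture_spec(2, 1, seed = 1))
  prods <- phosphorylate_library(data.frame(
    id = c("a", "b", "c"),
    smiles = c("Oc1ccccc1", "Oc1ccc(C)cc1", "Oc1ccc2ccccc2c1")))
  list(fx = fx, prods = prods)
}

test_that("the mock engine is deterministic and respects n_poses_max", {
  d <- make_dock_fixture()
  spec <- docking_job_spec(d$fx$receptor_path, c(1, 2, 3), c(20, 20, 20),
                           n_poses_max = 5L)
  wd1 <- tempfile(); wd2 <- tempfile()
  r1 <- run_docking(d$prods, spec, workdir = wd1)
  r2 <- run_docking(d$prods, spec, workdir = wd2)
  expect_length(r1$pose_sets, 3L)
  expect_equal(nrow(r1$failures), 0L)
  for (id in names(r1$pose_sets)) {
    expect_identical(readLines(file.path(wd1, paste0(id, ".pdbqt"))),
                     readLines(file.path(wd2, paste0(id, ".pdbqt"))))
  }
  for (ps in r1$pose_sets) {
    expect_lte(length(ps$models), 5L)
    sc <- vapply(ps$models, `[[`, 1, "score")
    expect_true(all(diff(sc) >= 0))
    expect_equal(vapply(ps$models, `[[`, 1L, "pose_index"),
                 seq_along(ps$models))
  }
})

test_that("the mock engine anchors the phosphate at the box center", {
  d <- make_dock_fixture()
  center <- c(4.5, -2.0, 7.25)
  spec <- docking_job_spec(d$fx$receptor_path, center, c(20, 20, 20))
  r <- run_docking(d$prods[1, ], spec, workdir = tempfile())
  atoms <- r$pose_sets[[1]]$models[[1]]$atoms
  p <- atoms[atoms$element == "P", ]
  expect_equal(unlist(p[, c("x", "y", "z")], use.names = FALSE), center,
               tolerance = 1e-6)
  # phosphate oxygens at covalent range from P
  grp <- locate_phosphate_atoms(atoms)
  expect_length(grp, 1L)
  expect_length(grp[[1]]$o_rows, 4L)
})

test_that("a failing external command yields per-ligand failure records", {
  d <- make_dock_fixture()
  spec <- docking_job_spec(d$fx$receptor_path, c(0, 0, 0), c(10, 10, 10),
                           engine = "external-command", engine_command = "false")
  r <- run_docking(d$prods, spec, workdir = tempfile())
  expect_length(r$pose_sets, 0L)
  expect_equal(nrow(r$failures), 3L)
  expect_equal(r$failures$ligand_id, d$prods$product_id)
})

test_that("a missing receptor is fatal before any docking", {
  d <- make_dock_fixture()
  spec <- docking_job_spec(tempfile(), c(0, 0, 0), c(10, 10, 10))
  expect_error(run_docking(d$prods, spec), class = "ps_error_io")
})

test_that("job specs validate box and engine parameters", {
  expect_error(docking_job_spec("r.pdb", c(0, 0), c(10, 10, 10)),
               class = "phosphoscreen_error")
  expect_error(docking_job_spec("r.pdb", c(0, 0, 0), c(10, -1, 10)),
               class = "phosphoscreen_error")
  expect_error(docking_job_spec("r.pdb", c(0, 0, 0), c(10, 10, 10),
                                engine = "external-command"),
               class = "phosphoscreen_error")
})

test_that("multi-model PDBQT files parse with scores and exact coordinates", {
  f <- two_model_pdbqt(tempfile(fileext = ".pdbqt"))
  ps <- parse_pose_file(f, "lig")
  expect_length(ps$models, 2L)
  expect_equal(vapply(ps$models, `[[`, 1, "score"), c(-7.1, -6.4))
  expect_equal(ps$models[[1]]$atoms$x, c(1, 1))
  expect_equal(ps$models[[1]]$atoms$z, c(3, 5.5))
  expect_equal(ps$models[[1]]$atoms$element, c("P", "O"))
})

test_that("a file without MODEL blocks is one model with score unset", {
  f <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  O1  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 O "), f)
  ps <- parse_pose_file(f)
  expect_length(ps$models, 1L)
  expect_true(is.na(ps$models[[1]]$score))
  expect_equal(nrow(ps$models[[1]]$atoms), 2L)
})

test_that("malformed coordinate records name the offending line", {
  f <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  C2  LIG A   1       x.xxx   0.000   0.000  1.00  0.00     0.000 C ",
    "ENDMDL"), f)
  err <- tryCatch(parse_pose_file(f), error = identity)
  expect_s3_class(err, "ps_error_parse")
  expect_match(conditionMessage(err), "line 3")
})

test_that("pose parse -> write -> parse is a fixed point", {
  f <- two_model_pdbqt(tempfile(fileext = ".pdbqt"))
  ps <- parse_pose_file(f, "lig")
  out <- tempfile(fileext = ".pdbqt")
  write_pose_file(ps, out)
  ps2 <- parse_pose_file(out, "lig")
  strip <- function(x) lapply(x$models, function(m) m[c("pose_index", "score", "atoms")])
  expect_identical(strip(ps2), strip(ps))
  # and writing again changes nothing byte-wise
  out2 <- tempfile(fileext = ".pdbqt")
  write_pose_file(ps2, out2)
  expect_identical(readLines(out2), readLines(out))
})
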