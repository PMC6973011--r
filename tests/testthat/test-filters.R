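test_that("phenolic hydroxyl counting distinguishes phenols from other oxygens", {
  expect_equal(count_phenolic_hydroxyls(
    c("Oc1ccccc1", "OC1CCCCC1", "Oc1ccc(O)cc1", "COc1ccccc1", "CC(=O)O")),
    c(1L, 0L, 2L, 0L, 0L))
})

test_that("reactive-moiety detection names the first matching pattern", {
  rx <- has_reactive_moiety(c("C=CC=O", "Oc1ccccc1", "ClCc1ccccc1"))
  expect_equal(rx$reactive, c(TRUE, FALSE, TRUE))
  expect_equal(rx$pattern, c("michael_acceptor", NA, "alkyl_halide"))
  # empty pattern set disables the stage
  rx0 <- has_reactive_moiety("C=CC=O", patterns = character(0))
  expect_false(rx0$reactive)
})

test_that("filter configuration validates its inputs", {
  expect_error(filter_config(mw_max = -1), class = "phosphoscreen_error")
  expect_error(filter_config(phenol_pattern = "[[bad"), class = "ps_error_smarts")
  expect_error(filter_config(reactive_patterns = c("C=O")),
               class = "phosphoscreen_error")  # unnamed
})

test_that("the MW gate is strictly below the bound", {
  f <- tempfile(fileext = ".smi")
  writeLines("Oc1ccccc1 phen", f)
  lib <- read_compound_library(f)
  at_bound <- filter_config(mw_max = molecular_weight("Oc1ccccc1"))
  res <- apply_fragment_filters(lib, at_bound)
  expect_equal(nrow(res$passed), 0L)
  dec <- res$decisions
  expect_equal(dec$stage[!dec$passed], "mw")
  above <- filter_config(mw_max = molecular_weight("Oc1ccccc1") + 0.01)
  expect_equal(nrow(apply_fragment_filters(lib, above)$passed), 1L)
})

test_that("an all-acyclic library fails entirely at the scaffold stage", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "CCCC b", "CC(C)O c"), f)
  lib <- read_compound_library(f)
  res <- apply_fragment_filters(lib)
  expect_equal(nrow(res$passed), 0L)
  expect_true(all(res$decisions$stage == "scaffold"))
  expect_true(all(!res$decisions$passed))
})

test_that("disabled stages pass everything through unchanged", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("Cc1ccccc1 tol", "ClCc1ccccc1 bcl"), f)
  lib <- read_compound_library(f)
  cfg <- filter_config(require_phenol = FALSE, reactive_patterns = character(0))
  res <- apply_fragment_filters(lib, cfg)
  fun <- as.data.frame(res$funnel)
  expect_equal(fun$n_in[fun$stage == "phenol"], fun$n_out[fun$stage == "phenol"])
  expect_equal(fun$n_in[fun$stage == "reactive"], fun$n_out[fun$stage == "reactive"])
  expect_equal(nrow(res$passed), 2L)
})

test_that("funnel is monotone, chains across stages, and validates", {
  g <- generate_library(library_spec(120, 40, 20, 20, 25, 15, seed = 21))
  lib <- read_compound_library(g$smi_path)
  res <- apply_fragment_filters(lib)
  fun <- as.data.frame(res$funnel)
  expect_true(all(fun$n_out <= fun$n_in))
  expect_equal(fun$n_in[-1L], fun$n_out[-nrow(fun)])
  expect_error(funnel_report(data.frame(stage = "x", n_in = 2, n_out = 5)),
               class = "phosphoscreen_error")
  expect_error(
    funnel_report(data.frame(stage = c("a", "b"), n_in = c(5, 4), n_out = c(3, 2))),
    class = "phosphoscreen_error")
})

test_that("re-filtering the pass set is the identity", {
  g <- generate_library(library_spec(120, 40, 20, 20, 25, 15, seed = 22))
  lib <- read_compound_library(g$smi_path)
  res <- apply_fragment_filters(lib)
  res2 <- apply_fragment_filters(res$passed)
  expect_equal(res2$passed$id, res$passed$id)
  expect_equal(res2$passed$smiles, res$passed$smiles)
})

test_that("the pass set is the intersection of independent stage predicates", {
  g <- generate_library(library_spec(100, 30, 20, 15, 20, 15, seed = 23))
  lib <- read_compound_library(g$smi_path)
  cfg <- filter_config()
  res <- apply_fragment_filters(lib, cfg)
  scaffold_p <- vapply(lib$smiles, function(s)
    matches_scaffold_set(s, cfg$scaffold_set)$match, TRUE, USE.NAMES = FALSE)
  phenol_p <- count_phenolic_hydroxyls(lib$smiles, cfg$phenol_pattern) >= 1L
  mw_p <- molecular_weight(lib$smiles) < cfg$mw_max
  react_p <- !has_reactive_moiety(lib$smiles, cfg$reactive_patterns)$reactive
  expected <- lib$id[scaffold_p & phenol_p & mw_p & react_p]
  expect_setequal(res$passed$id, expected)
})

test_that("decision records carry first failure or one pass row per stage", {
  g <- generate_library(library_spec(60, 20, 10, 10, 10, 10, seed = 24))
  lib <- read_compound_library(g$smi_path)
  res <- apply_fragment_filters(lib)
  dec <- res$decisions
  per_id <- split(dec, dec$id)
  for (id in names(per_id)) {
    d <- per_id[[id]]
    if (id %in% res$passed$id) {
      expect_true(all(d$passed))
      expect_setequal(d$stage, c("parse", "scaffold", "phenol", "mw", "reactive"))
    } else {
      expect_equal(nrow(d), 1L)
      expect_false(d$passed)
    }
  }
})
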