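test_that("ring scaffold extraction removes side chains, keeps ring systems", {
  expect_true(canon_eq(extract_ring_scaffold("Oc1ccc(-c2ccccc2)cc1"),
                       "c1ccc(-c2ccccc2)cc1"))
  expect_true(canon_eq(extract_ring_scaffold("Cc1ccccc1"), "c1ccccc1"))
  expect_true(is.na(extract_ring_scaffold("CCCC")))
  expect_error(extract_ring_scaffold("C1CC"), class = "ps_error_parse")
})

test_that("exocyclic double bonds on the framework survive extraction", {
  # a substituted chromone must keep its ring carbonyl
  expect_true(canon_eq(extract_ring_scaffold("CCc1cc(=O)c2ccccc2o1"),
                       "O=C1C=COc2ccccc21"))
  # but a whole side chain ending in a carbonyl is removed
  expect_true(canon_eq(extract_ring_scaffold("CC(=O)c1ccccc1"), "c1ccccc1"))
})

test_that("parent-scaffold iteration walks down to single rings", {
  bip <- iterate_parent_scaffolds("c1ccc(-c2ccccc2)cc1")
  expect_length(bip, 2L)
  expect_true(canon_eq(bip[1], "c1ccc(-c2ccccc2)cc1"))
  expect_true(canon_eq(bip[2], "c1ccccc1"))

  nap <- iterate_parent_scaffolds("c1ccc2ccccc2c1")
  expect_length(nap, 2L)
  expect_true(canon_eq(nap[2], "c1ccccc1"))

  benz <- iterate_parent_scaffolds("c1ccccc1")
  expect_length(benz, 1L)
  expect_identical(iterate_parent_scaffolds("CCCC"), character(0))
})

test_that("fused aromatic removal leaves an aromatic ring, saturated stays saturated", {
  # tetralin: removing either peripheral ring must not aromatize the rest
  tet <- iterate_parent_scaffolds("C1CCc2ccccc2C1")
  expect_true(any(vapply(tet, canon_eq, TRUE, b = "c1ccccc1")))
  expect_true(any(vapply(tet, canon_eq, TRUE, b = "C1CCCCC1")))
})

test_that("scaffold-set matching follows the parent chain in exact mode", {
  s <- scaffold_set(c(biphenyl = "c1ccc(-c2ccccc2)cc1"))
  m <- matches_scaffold_set("Oc1ccc(-c2ccccc2)cc1", s)
  expect_true(m$match)
  expect_equal(m$name, "biphenyl")

  s2 <- scaffold_set(c(benzene = "c1ccccc1"))
  expect_true(matches_scaffold_set("Oc1ccccc1", s2)$match)
  expect_false(matches_scaffold_set("CCO", s2)$match)
  # a biphenyl compound reaches benzene through the parent chain
  expect_true(matches_scaffold_set("Oc1ccc(-c2ccccc2)cc1", s2)$match)
})

test_that("substructure mode matches SMARTS entries directly", {
  s <- scaffold_set(c(indole = "c1ccc2[nH]ccc2c1"), matching_mode = "substructure")
  expect_true(matches_scaffold_set("Cc1c[nH]c2ccccc12", s)$match)
  expect_false(matches_scaffold_set("c1ccccc1", s)$match)
})

test_that("scaffold sets validate their entries", {
  expect_error(scaffold_set(c(acyclic = "CCO")), class = "phosphoscreen_error")
  expect_error(scaffold_set(c("c1ccccc1")), class = "phosphoscreen_error")
  expect_error(scaffold_set(c(a = "c1ccccc1", a = "c1ccncc1")),
               class = "phosphoscreen_error")
  expect_error(scaffold_set(c(bad = "not(S")), class = "phosphoscreen_error")
})

test_that("the default scaffold set entries are their own scaffolds", {
  s <- default_scaffold_set()
  for (nm in names(s$entries)) {
    ext <- extract_ring_scaffold(s$entries[[nm]])
    expect_false(is.na(ext), info = nm)
    expect_true(canon_eq(ext, s$entries[[nm]]), info = nm)
  }
})
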