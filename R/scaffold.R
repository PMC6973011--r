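# Scaffold extraction and natural-product structural-element matching.
#
# A molecule's ring scaffold is its Murcko framework: all rings plus the
# linkers connecting them, side chains removed, keeping atoms double- or
# triple-bonded to the framework (so ring carbonyls such as the chromone oxo
# group survive). Parent scaffolds are obtained by iteratively deleting one
# peripheral ring at a time; a compound carries a natural-product structural
# element when any scaffold in that chain equals a scaffold-set entry.

#' Extract the ring scaffold (Murcko framework) of a molecule
#'
#' @param smiles A single SMILES string.
#' @return Canonical SMILES of the framework, or `NA` for acyclic molecules.
#' @examples
#' extract_ring_scaffold("Oc1ccc(-c2ccccc2)cc1")  # biphenyl
#' extract_ring_scaffold("CCCC")                  # NA
#' @export
extract_ring_scaffold <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) ps_stop(sprintf("cannot parse SMILES '%s'", smiles), "ps_error_parse")
  memo("scaffold", can, function() {
    g <- smiles_to_molgraph(can)
    keep <- murcko_keep(g)
    if (!length(keep)) return(NA_character_)
    molgraph_to_smiles(mg_take(g, keep))
  })
}

# Direct parents of one scaffold: delete each peripheral ring (a ring sharing
# at most one bond with the remaining ring system), re-prune dangling linkers,
# demote orphaned aromatic bonds, canonicalize.
#' @noRd
direct_parent_scaffolds <- function(scaffold) {
  memo("parents", scaffold, function() {
    g <- smiles_to_molgraph(scaffold)
    rings <- mol_rings(g)
    if (length(rings) <= 1L) return(character(0))
    out <- character(0)
    for (k in seq_along(rings)) {
      ring <- rings[[k]]
      others <- rings[-k]
      other_atoms <- unique(unlist(others))
      other_bonds <- unique(unlist(lapply(others, ring_bond_rows, g = g)))
      shared <- intersect(ring_bond_rows(g, ring), other_bonds)
      if (length(shared) > 1L) next
      excl <- setdiff(ring, other_atoms)
      if (!length(excl)) next
      keep <- setdiff(seq_len(nrow(g$atoms)), excl)
      g2 <- demote_orphan_aromatic(mg_take(g, keep))
      keep2 <- murcko_keep(g2)
      if (!length(keep2)) next
      g2 <- mg_take(g2, keep2)
      smi <- tryCatch(molgraph_to_smiles(g2), error = function(e) NA_character_)
      if (!is.na(smi)) out <- c(out, smi)
    }
    unique(out)
  })
}

#' Enumerate a scaffold and all its parent scaffolds
#'
#' Walks the scaffold tree from the given ring scaffold down to single-ring
#' scaffolds by removing one peripheral ring at a time (a peripheral ring
#' shares at most one bond with the rest of the ring system). The result is
#' finite and de-duplicated by canonical SMILES, and always contains the
#' input scaffold itself.
#'
#' @param scaffold Scaffold SMILES (must contain at least one ring).
#' @return Character vector of canonical scaffold SMILES; `character(0)` for
#'   acyclic input.
#' @examples
#' iterate_parent_scaffolds("c1ccc(-c2ccccc2)cc1")  # biphenyl, benzene
#' @export
iterate_parent_scaffolds <- function(scaffold) {
  stopifnot(length(scaffold) == 1L)
  can <- canonical_smiles(scaffold)
  if (is.na(can)) ps_stop(sprintf("cannot parse SMILES '%s'", scaffold), "ps_error_parse")
  root <- extract_ring_scaffold(can)
  if (is.na(root)) return(character(0))
  seen <- character(0)
  queue <- root
  while (length(queue)) {
    s <- queue[[1L]]
    queue <- queue[-1L]
    if (s %in% seen) next
    seen <- c(seen, s)
    queue <- c(queue, setdiff(direct_parent_scaffolds(s), seen))
  }
  seen
}

#' Define a scaffold set
#'
#' @param entries Named character vector (or named list) of SMILES/SMARTS
#'   patterns, one per structural element. Names must be unique; every
#'   pattern must parse and contain at least one ring.
#' @param matching_mode `"exact-scaffold"`: a compound matches when any
#'   element of its parent-scaffold chain canonically equals an entry.
#'   `"substructure"`: a compound matches when it contains an entry as a
#'   substructure (entries treated as SMARTS).
#' @return A `scaffold_set` object.
#' @seealso [default_scaffold_set()]
#' @export
scaffold_set <- function(entries, matching_mode = c("exact-scaffold", "substructure")) {
  matching_mode <- match.arg(matching_mode)
  entries <- unlist(entries)
  ps_assert(length(entries) > 0L, "scaffold set must not be empty")
  nm <- names(entries)
  ps_assert(!is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm),
            "scaffold set entries must have unique names")
  canon <- rep(NA_character_, length(entries))
  if (matching_mode == "exact-scaffold") {
    for (i in seq_along(entries)) {
      can <- canonical_smiles(entries[[i]])
      ps_assert(!is.na(can), sprintf("scaffold '%s' does not parse as SMILES", nm[i]),
                "ps_error_parse")
      # canonicalize through the same graph round trip as extracted scaffolds
      canon[i] <- molgraph_to_smiles(smiles_to_molgraph(can))
      ps_assert(length(mol_rings(smiles_to_molgraph(canon[i]))) >= 1L,
                sprintf("scaffold '%s' contains no ring", nm[i]))
    }
  } else {
    for (i in seq_along(entries)) {
      validate_smarts(entries[[i]], sprintf("scaffold pattern '%s'", nm[i]))
      ps_assert(grepl("1", entries[[i]], fixed = TRUE),
                sprintf("scaffold pattern '%s' contains no ring", nm[i]))
    }
    canon <- unname(entries)
  }
  structure(list(entries = stats::setNames(unname(entries), nm),
                 canonical = stats::setNames(canon, nm),
                 matching_mode = matching_mode),
            class = "scaffold_set")
}

#' Default natural-product structural-element set
#'
#' A small, documented, fully replaceable stand-in for a natural-product
#' scaffold tree: benzene, biphenyl, naphthalene, indole, chromone, flavone,
#' coumarin, quinoline, purine, and the steroid tetracycle (gonane), matched
#' in exact-scaffold mode with parent-scaffold traversal.
#'
#' @return A `scaffold_set`.
#' @export
default_scaffold_set <- function() {
  scaffold_set(c(
    benzene     = "c1ccccc1",
    biphenyl    = "c1ccc(-c2ccccc2)cc1",
    naphthalene = "c1ccc2ccccc2c1",
    indole      = "c1ccc2[nH]ccc2c1",
    chromone    = "O=C1C=COc2ccccc21",
    flavone     = "O=C1C=C(c2ccccc2)Oc2ccccc21",
    coumarin    = "O=C1C=Cc2ccccc2O1",
    quinoline   = "c1ccc2ncccc2c1",
    purine      = "c1ncc2[nH]cnc2n1",
    steroid     = "C1CCC2C(C1)CCC1C2CCC2CCCC12"
  ), matching_mode = "exact-scaffold")
}

#' Test a molecule against a scaffold set
#'
#' @param smiles A single SMILES string.
#' @param set A [scaffold_set()].
#' @return A list with `match` (logical) and `name` (matched entry name or
#'   `NA`). Acyclic molecules never match and never error.
#' @examples
#' s <- scaffold_set(c(biphenyl = "c1ccc(-c2ccccc2)cc1"))
#' matches_scaffold_set("Oc1ccc(-c2ccccc2)cc1", s)
#' @export
matches_scaffold_set <- function(smiles, set) {
  stopifnot(inherits(set, "scaffold_set"), length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) ps_stop(sprintf("cannot parse SMILES '%s'", smiles), "ps_error_parse")
  if (set$matching_mode == "exact-scaffold") {
    chain <- iterate_parent_scaffolds(can)
    if (!length(chain)) return(list(match = FALSE, name = NA_character_))
    hit <- match(set$canonical, chain)
    if (all(is.na(hit))) return(list(match = FALSE, name = NA_character_))
    # report the entry matched earliest in the chain (largest scaffold first)
    best <- which.min(replace(hit, is.na(hit), Inf))
    list(match = TRUE, name = names(set$canonical)[best])
  } else {
    for (i in seq_along(set$entries)) {
      if (smarts_count(can, set$entries[[i]]) > 0L) {
        return(list(match = TRUE, name = names(set$entries)[i]))
      }
    }
    list(match = FALSE, name = NA_character_)
  }
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d entries, %s matching\n",
              length(x$entries), x$matching_mode))
  for (nm in names(x$entries)) cat(sprintf("  %-12s %s\n", nm, x$entries[[nm]]))
  invisible(x)
}
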