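# Virtual O-phosphorylation: replace a phenolic O-H with O-PO(OH)2 by editing
# the molecular graph, and the reverse transform for round-trip verification.
# Products are written as the neutral dihydrogen phosphate; protonation-state
# assignment is a docking-preparation concern handled downstream.

# Monoisotopic mass gain per phosphate introduced (HPO3).
MASS_DELTA_PHOSPHO <- 79.96633

#' Phosphorylation policy
#'
#' @param mode How to handle multiple phenolic sites:
#'   `"enumerate-all-sites"` (one product per distinct site),
#'   `"first-site-only"` (one product at the lowest canonical atom index), or
#'   `"error-on-multiple"` (raise when more than one site exists).
#' @param dedupe_symmetric Drop products that canonicalize to the same SMILES
#'   (symmetry-equivalent sites); default `TRUE`.
#' @return A `phospho_policy` object.
#' @export
phospho_policy <- function(mode = c("enumerate-all-sites", "first-site-only",
                                    "error-on-multiple"),
                           dedupe_symmetric = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, dedupe_symmetric = isTRUE(dedupe_symmetric)),
            class = "phospho_policy")
}

# Phenolic oxygens in a molecular graph (fully explicit H): neutral O bound
# to exactly one aromatic carbon and one hydrogen.
#' @noRd
phenolic_site_indices <- function(g) {
  cand <- integer(0)
  for (i in which(g$atoms$element == "O" & g$atoms$charge == 0L)) {
    nbr <- mg_neighbors(g, i)
    if (length(nbr) != 2L) next
    els <- g$atoms$element[nbr]
    if (sum(els == "H") != 1L) next
    heavy <- nbr[els != "H"]
    if (g$atoms$type[heavy] == "C.ar") cand <- c(cand, i)
  }
  cand
}

# Swap the hydroxyl hydrogen at `site` for a -PO(OH)2 group, with explicit
# hydrogens on the two new hydroxyl oxygens.
#' @noRd
attach_phosphate <- function(g, site) {
  nbr <- mg_neighbors(g, site)
  h <- nbr[g$atoms$element[nbr] == "H"][1L]
  keep <- setdiff(seq_len(nrow(g$atoms)), h)
  site_new <- match(site, keep)
  g <- mg_subgraph(g, keep)
  na <- nrow(g$atoms)
  g$atoms <- rbind(g$atoms,
                   data.frame(element = c("P", "O", "O", "O"),
                              type = c("P.3", "O.2", "O.3", "O.3"),
                              charge = 0L, stringsAsFactors = FALSE))
  g$bonds <- rbind(g$bonds,
                   data.frame(a1 = c(site_new, na + 1L, na + 1L, na + 1L),
                              a2 = na + 1:4,
                              type = c("1", "2", "1", "1"),
                              stringsAsFactors = FALSE))
  g <- mg_add_h(g, na + 3L)
  g <- mg_add_h(g, na + 4L)
  g
}

#' Virtually O-phosphorylate the phenolic hydroxyls of a molecule
#'
#' Each product replaces one phenolic O-H with O-P(=O)(OH)(OH), written as
#' the neutral dihydrogen phosphate ester. A molecule without phenolic sites
#' yields an empty product table (it is never returned unchanged).
#'
#' @param smiles A single SMILES string (normalized internally).
#' @param policy A [phospho_policy()].
#' @param parent_id Identifier recorded in the product table.
#' @return A data.frame with columns `parent_id`, `product_id`,
#'   `product_smiles` (canonical), `site_index` (atom index of the
#'   phosphorylated oxygen in the parent's canonical atom order), and
#'   `mass_delta_mono` (monoisotopic mass gain in Da).
#' @examples
#' phosphorylate_phenols("Oc1ccccc1")
#' @export
phosphorylate_phenols <- function(smiles, policy = phospho_policy(),
                                  parent_id = "parent") {
  stopifnot(length(smiles) == 1L, inherits(policy, "phospho_policy"))
  parent <- normalize_compound(smiles)
  g <- smiles_to_molgraph(parent)
  sites <- phenolic_site_indices(g)
  empty <- data.frame(parent_id = character(0), product_id = character(0),
                      product_smiles = character(0), site_index = integer(0),
                      mass_delta_mono = numeric(0), stringsAsFactors = FALSE)
  if (!length(sites)) return(empty)
  if (policy$mode == "error-on-multiple" && length(sites) > 1L) {
    ps_stop(sprintf("%d phenolic sites in '%s' under error-on-multiple policy",
                    length(sites), parent), "ps_error_multisite")
  }
  if (policy$mode == "first-site-only") sites <- sites[1L]
  prods <- vapply(sites, function(s) molgraph_to_smiles(attach_phosphate(g, s)), "")
  if (policy$dedupe_symmetric) {
    keep <- !duplicated(prods)
    prods <- prods[keep]
    sites <- sites[keep]
  }
  masses <- monoisotopic_mass(c(parent, prods))
  data.frame(
    parent_id = parent_id,
    product_id = sprintf("%s_p%d", parent_id, sites),
    product_smiles = prods,
    site_index = sites,
    mass_delta_mono = masses[-1L] - masses[1L],
    stringsAsFactors = FALSE
  )
}

#' Phosphorylate every compound of a library
#'
#' @param library A `compound_library` (or data.frame with `id`, `smiles`).
#' @param policy A [phospho_policy()].
#' @return The row-bound product table of [phosphorylate_phenols()] across
#'   the library, parents in input order.
#' @export
phosphorylate_library <- function(library, policy = phospho_policy()) {
  out <- lapply(seq_len(nrow(library)), function(i) {
    phosphorylate_phenols(library$smiles[i], policy, parent_id = library$id[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Aryl dihydrogen-phosphate groups (explicit hydrogens): P with four oxygen
# bonds — one P=O, two terminal P-OH, and one ester O leading to an aromatic
# carbon. Removal covers the P, the three terminal oxygens, and their H.
#' @noRd
aryl_phosphate_groups <- function(g) {
  groups <- list()
  for (p in which(g$atoms$element == "P")) {
    rows <- mg_bond_rows(g, p)
    if (length(rows) != 4L) next
    nbr <- ifelse(g$bonds$a1[rows] == p, g$bonds$a2[rows], g$bonds$a1[rows])
    if (!all(g$atoms$element[nbr] == "O")) next
    dbl <- g$bonds$type[rows] == "2"
    kind <- character(4L)
    others <- vector("list", 4L)
    for (k in seq_len(4L)) {
      o <- nbr[k]
      rest <- setdiff(mg_neighbors(g, o), p)
      others[[k]] <- rest
      rest_el <- g$atoms$element[rest]
      kind[k] <- if (dbl[k] && !length(rest)) "oxo"
        else if (!dbl[k] && all(rest_el == "H") && length(rest) <= 1L &&
                 g$atoms$charge[o] == 0L) "hydroxyl"
        else if (!dbl[k] && length(rest) == 1L && rest_el != "H") "ester"
        else "other"
    }
    if (sum(kind == "oxo") != 1L || sum(kind == "hydroxyl") != 2L ||
        sum(kind == "ester") != 1L) next
    carbon <- others[[which(kind == "ester")]]
    if (g$atoms$type[carbon] != "C.ar") next
    drop <- c(p, nbr[kind != "ester"],
              unlist(others[kind == "hydroxyl"]))
    groups[[length(groups) + 1L]] <- list(p = p, remove = drop,
                                          ester_o = nbr[kind == "ester"])
  }
  groups
}

#' Remove aryl dihydrogen-phosphate groups (reverse transform)
#'
#' Reverts every aryl O-PO(OH)2 group to the parent phenol; used for
#' round-trip verification of the phosphorylation transform.
#'
#' @param smiles A single SMILES string containing at least one aryl
#'   dihydrogen phosphate.
#' @return Canonical SMILES of the dephosphorylated molecule.
#' @examples
#' dephosphorylate("O=P(O)(O)Oc1ccccc1")
#' @export
dephosphorylate <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  can <- normalize_compound(smiles)
  g <- smiles_to_molgraph(can)
  groups <- aryl_phosphate_groups(g)
  if (!length(groups)) {
    ps_stop(sprintf("no aryl dihydrogen-phosphate group in '%s'", smiles),
            "ps_error_no_phosphate")
  }
  remove <- unique(unlist(lapply(groups, `[[`, "remove")))
  esters <- vapply(groups, `[[`, 1L, "ester_o")
  keep <- setdiff(seq_len(nrow(g$atoms)), remove)
  g2 <- mg_subgraph(g, keep)
  for (o in match(esters, keep)) g2 <- mg_add_h(g2, o)  # restore the phenol O-H
  canonical_smiles(molgraph_to_smiles(g2))
}
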