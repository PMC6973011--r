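# Internal chemistry backend.
#
# All chemical perception (SMILES parsing, canonicalization, aromaticity,
# implicit hydrogens, SMARTS matching, masses) is delegated to OpenBabel via
# ChemmineOB/ChemmineR. Structure edits (phosphorylation, scaffold pruning)
# operate on a light molecular-graph representation exchanged with OpenBabel
# as MOL2 text, because MOL2 carries OB's aromaticity assignment (.ar atom
# types, "ar" bonds) and formal charges (UNITY_ATOM_ATTR records), so edited
# graphs re-enter OB without any hand-rolled valence model.

ob_noopts <- data.frame(names = character(0), args = character(0))

# -- vectorized canonicalization ---------------------------------------------

# Canonical SMILES for a character vector; NA for entries OpenBabel rejects.
# OB stops a batch conversion at the first molecule it cannot parse, so each
# entry is tagged with its index as the molecule title and conversion resumes
# past the offender until the whole batch is accounted for.
#' @noRd
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(ok)
  start <- 1L
  while (start <= length(idx)) {
    span <- idx[start:length(idx)]
    inp <- paste(paste(smiles[span], seq_along(span)), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", inp, options = ob_noopts)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[`, "", 1L)
      tag <- suppressWarnings(as.integer(
        vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")))
      keep <- !is.na(tag) & nzchar(can)
      out[span[tag[keep]]] <- can[keep]
      got <- tag[keep]
    }
    if (length(got) == length(span)) break
    # first entry OB never produced is the parse failure; resume after it
    failed <- min(setdiff(seq_along(span), got))
    out[span[failed]] <- NA_character_
    start <- start + failed
  }
  out
}

#' @noRd
is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

# -- OBMol handles and SMARTS -------------------------------------------------

# Parse valid SMILES into OBMol references (one call into OB for the batch).
#' @noRd
ob_molrefs <- function(smiles) {
  if (length(smiles) == 0L) return(list())
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

# Count unique SMARTS matches per molecule. `smiles` must all be valid.
#' @noRd
smarts_count <- function(smiles, pattern, molrefs = NULL) {
  if (length(smiles) == 0L) return(integer(0))
  refs <- molrefs %||% ob_molrefs(smiles)
  vapply(refs, function(m) as.integer(ChemmineOB::smartsSearch_OB(list(m), pattern)), 1L)
}

# Fail fast on malformed SMARTS so filter configs are validated up front.
#' @noRd
validate_smarts <- function(pattern, what = "SMARTS pattern") {
  probe <- ob_molrefs("Oc1ccccc1")
  res <- tryCatch(ChemmineOB::smartsSearch_OB(probe, pattern),
                  error = function(e) NA)
  if (length(res) != 1L || is.na(res)) {
    ps_stop(sprintf("invalid %s: '%s'", what, pattern), "ps_error_smarts")
  }
  invisible(TRUE)
}

# -- masses ------------------------------------------------------------------

# Average molecular weight (standard atomic weights, implicit H included),
# computed by OpenBabel; NA for unparseable entries.
#' @noRd
average_mw <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_real_, n)
  if (n == 0L) return(out)
  can <- canonical_smiles(smiles)
  ok <- !is.na(can)
  if (!any(ok)) return(out)
  idx <- which(ok)
  inp <- paste(paste(can[idx], seq_along(idx)), collapse = "\n")
  res <- ChemmineOB::convertFormat("SMI", "TXT", inp,
                                   options = data.frame(names = "append", args = "MW"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    tag <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(parts, function(p) p[length(p)], "")))
    keep <- !is.na(tag) & !is.na(val)
    out[idx[tag[keep]]] <- val[keep]
  }
  out
}

# Monoisotopic (exact) mass; `smiles` must all be valid.
#' @noRd
monoisotopic_mass <- function(smiles) {
  if (length(smiles) == 0L) return(numeric(0))
  as.numeric(ChemmineOB::exactMass_OB(ob_molrefs(smiles)))
}

# -- molecular graphs via MOL2 ------------------------------------------------

#' @noRd
new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

#' @noRd
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sect <- grep("^@<TRIPOS>", lines)
  name <- sub("^@<TRIPOS>", "", lines[sect])
  block <- function(what) {
    i <- match(what, name)
    if (is.na(i)) return(character(0))
    from <- sect[i] + 1L
    to <- if (i < length(sect)) sect[i + 1L] - 1L else length(lines)
    if (from > to) return(character(0))
    out <- lines[from:to]
    out[nzchar(trimws(out))]
  }
  at <- block("ATOM")
  if (!length(at)) ps_stop("MOL2 text contains no atoms", "ps_error_parse")
  af <- strsplit(trimws(at), "[[:space:]]+")
  type <- vapply(af, `[`, "", 6L)
  atoms <- data.frame(
    element = sub("\\..*$", "", type),
    type = type,
    charge = 0L,
    stringsAsFactors = FALSE
  )
  bd <- block("BOND")
  if (length(bd)) {
    bf <- strsplit(trimws(bd), "[[:space:]]+")
    bonds <- data.frame(
      a1 = as.integer(vapply(bf, `[`, "", 2L)),
      a2 = as.integer(vapply(bf, `[`, "", 3L)),
      type = vapply(bf, `[`, "", 4L),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), type = character(0),
                        stringsAsFactors = FALSE)
  }
  ua <- block("UNITY_ATOM_ATTR")
  i <- 1L
  while (i < length(ua)) {
    hd <- strsplit(trimws(ua[i]), "[[:space:]]+")[[1]]
    aid <- as.integer(hd[1L]); nattr <- as.integer(hd[2L])
    for (k in seq_len(nattr)) {
      kv <- strsplit(trimws(ua[i + k]), "[[:space:]]+")[[1]]
      if (identical(kv[1L], "charge")) atoms$charge[aid] <- as.integer(kv[2L])
    }
    i <- i + 1L + nattr
  }
  new_molgraph(atoms, bonds)
}

#' @noRd
write_mol2 <- function(g) {
  na <- nrow(g$atoms); nb <- nrow(g$bonds)
  atom_lines <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-6s %3d UNL1 %9.4f",
                        seq_len(na), g$atoms$element, 0, 0, 0, g$atoms$type,
                        1L, 0)
  bond_lines <- if (nb) {
    sprintf("%6d %5d %5d %4s", seq_len(nb), g$bonds$a1, g$bonds$a2, g$bonds$type)
  } else character(0)
  charged <- which(g$atoms$charge != 0L)
  attr_lines <- if (length(charged)) {
    c("@<TRIPOS>UNITY_ATOM_ATTR",
      unlist(lapply(charged, function(i) c(sprintf("%d 1", i),
                                           sprintf("charge %d", g$atoms$charge[i])))))
  } else character(0)
  paste(c("@<TRIPOS>MOLECULE", "phosphoscreen",
          sprintf(" %d %d 0 0 0", na, nb),
          "SMALL", "NO_CHARGES", "",
          "@<TRIPOS>ATOM", atom_lines,
          attr_lines,
          "@<TRIPOS>BOND", bond_lines, ""),
        collapse = "\n")
}

# Atom order of the resulting graph follows the SMILES atom order, which for
# canonical input is the molecule's canonical atom order; explicit hydrogens
# are appended after the heavy atoms.
#
# Hydrogen policy: MOL2 has no implicit-hydrogen field, and once a molecule
# carries any explicit hydrogen OpenBabel's reader stops refilling valence
# anywhere (a pruned phenol oxygen would come back as an alkoxide, a pyrrole
# nitrogen H-less). Graphs are therefore fully explicit-H, and every edit
# below maintains the hydrogen count itself.
#' @noRd
smiles_to_molgraph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  txt <- ChemmineOB::convertFormat("SMI", "MOL2", smiles,
                                   options = data.frame(names = "h", args = ""))
  if (!grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)) {
    ps_stop(sprintf("cannot parse SMILES '%s'", smiles), "ps_error_parse")
  }
  parse_mol2(txt)
}

# order contributed by one bond of a given MOL2 type
#' @noRd
bond_order_equiv <- function(type) {
  ifelse(type == "2", 2L, ifelse(type == "3", 3L, 1L))
}

#' @noRd
mg_add_h <- function(g, at, n = 1L) {
  for (k in seq_len(n)) {
    g$atoms <- rbind(g$atoms, data.frame(element = "H", type = "H", charge = 0L,
                                         stringsAsFactors = FALSE))
    g$bonds <- rbind(g$bonds, data.frame(a1 = at, a2 = nrow(g$atoms),
                                         type = "1", stringsAsFactors = FALSE))
  }
  g
}

# Take a subset of atoms and repair hydrogen bookkeeping: hydrogens of
# removed atoms go too, and every kept heavy atom receives one explicit H per
# unit of bond order it lost to removed heavy neighbors (graphs are fully
# explicit-H; the MOL2 reader refills nothing).
#' @noRd
mg_take <- function(g, keep) {
  keep <- sort(unique(keep))
  hvec <- mg_is_h(g)
  orphan_h <- vapply(keep, function(i) {
    hvec[i] && !all(mg_neighbors(g, i) %in% keep)
  }, TRUE)
  keep <- keep[!orphan_h]
  lost <- vapply(keep, function(i) {
    if (hvec[i]) return(0L)
    rows <- mg_bond_rows(g, i)
    nb <- ifelse(g$bonds$a1[rows] == i, g$bonds$a2[rows], g$bonds$a1[rows])
    cut <- !(nb %in% keep) & g$atoms$element[nb] != "H"
    sum(bond_order_equiv(g$bonds$type[rows])[cut])
  }, 1L)
  g2 <- mg_subgraph(g, keep)
  for (i in which(lost > 0L)) g2 <- mg_add_h(g2, i, lost[i])
  g2
}

#' @noRd
mg_is_h <- function(g) g$atoms$element == "H"

#' @noRd
mg_heavy_count <- function(g) sum(!mg_is_h(g))

# Row indices of bonds incident to atom i.
#' @noRd
mg_bond_rows <- function(g, i) which(g$bonds$a1 == i | g$bonds$a2 == i)

# Neighbor atom indices of atom i.
#' @noRd
mg_neighbors <- function(g, i) {
  rows <- mg_bond_rows(g, i)
  ifelse(g$bonds$a1[rows] == i, g$bonds$a2[rows], g$bonds$a1[rows])
}

# Canonical SMILES of an edited graph. The graph carries no coordinates, so
# any stereo descriptors OpenBabel derives from the placeholder geometry are
# artifacts; they are stripped and the result re-canonicalized. Edited
# structures are therefore emitted without stereochemistry.
#' @noRd
molgraph_to_smiles <- function(g) {
  res <- ChemmineOB::convertFormat("MOL2", "CAN", write_mol2(g), options = ob_noopts)
  smi <- sub("[\t ].*$", "", sub("\n.*$", "", res))
  if (!nzchar(smi)) ps_stop("edited structure failed to canonicalize", "ps_error_parse")
  if (grepl("[@/\\\\]", smi)) {
    smi <- canonical_smiles(gsub("@|/|\\\\", "", smi))
    if (is.na(smi)) ps_stop("edited structure failed to canonicalize", "ps_error_parse")
  }
  smi
}

# -- graph utilities ----------------------------------------------------------

#' @noRd
mg_igraph <- function(g, bond_rows = seq_len(nrow(g$bonds))) {
  gi <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (length(bond_rows)) {
    e <- as.vector(t(as.matrix(g$bonds[bond_rows, c("a1", "a2")])))
    gi <- igraph::add_edges(gi, e)
  }
  gi
}

# Keep a subset of atoms, dropping bonds touching removed atoms; reindexes.
#' @noRd
mg_subgraph <- function(g, keep) {
  keep <- sort(unique(keep))
  map <- integer(nrow(g$atoms))
  map[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  rownames(b) <- NULL
  new_molgraph(g$atoms[keep, , drop = FALSE], b)
}

# Atom indices of the Murcko framework: iteratively prune degree-1 (and
# isolated) heavy atoms, re-attach heavy atoms joined to the framework by a
# double or triple bond (keeps ring carbonyls such as the chromone oxo
# group), then re-attach the hydrogens of kept atoms (keeps pyrrole N-H).
#' @noRd
murcko_keep <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L || nrow(g$bonds) == 0L) return(integer(0))
  hyd <- mg_is_h(g)
  keep <- !hyd
  repeat {
    inb <- keep[g$bonds$a1] & keep[g$bonds$a2]
    deg <- tabulate(c(g$bonds$a1[inb], g$bonds$a2[inb]), nbins = n)
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(integer(0))
  mult <- g$bonds$type %in% c("2", "3") & !hyd[g$bonds$a1] & !hyd[g$bonds$a2]
  readd <- c(g$bonds$a2[mult & keep[g$bonds$a1] & !keep[g$bonds$a2]],
             g$bonds$a1[mult & keep[g$bonds$a2] & !keep[g$bonds$a1]])
  keep[readd] <- TRUE
  h_att <- hyd[g$bonds$a1] & keep[g$bonds$a2]
  h_att2 <- hyd[g$bonds$a2] & keep[g$bonds$a1]
  sort(unique(c(which(keep), g$bonds$a1[h_att], g$bonds$a2[h_att2])))
}

# Demote aromatic bonds that no longer lie on any cycle of the aromatic-bond
# subgraph (they lost their ring) to single bonds, re-type their atoms, and
# top the demoted atoms up with explicit hydrogens to their standard valence
# (C 4, N 3+q, O 2+q, S 2) — the saturated-repair rule for broken rings.
#' @noRd
demote_orphan_aromatic <- function(g) {
  arb <- which(g$bonds$type == "ar")
  if (!length(arb)) return(g)
  gi <- mg_igraph(g, arb)
  br <- as.integer(igraph::bridges(gi))
  if (length(br)) g$bonds$type[arb[br]] <- "1"
  still_ar <- unique(c(g$bonds$a1[g$bonds$type == "ar"],
                       g$bonds$a2[g$bonds$type == "ar"]))
  fix <- which(grepl("\\.ar$", g$atoms$type) & !(seq_len(nrow(g$atoms)) %in% still_ar))
  for (i in fix) {
    el <- g$atoms$element[i]
    myb <- g$bonds$type[mg_bond_rows(g, i)]
    g$atoms$type[i] <- if (el %in% c("C", "N")) {
      if (any(myb == "3")) paste0(el, ".1")
      else if (any(myb == "2")) paste0(el, ".2")
      else paste0(el, ".3")
    } else if (el %in% c("O", "S")) {
      if (any(myb == "2")) paste0(el, ".2") else paste0(el, ".3")
    } else el
    target <- switch(el,
                     C = 4L, N = 3L + g$atoms$charge[i],
                     O = 2L + g$atoms$charge[i], S = 2L, NA_integer_)
    if (!is.na(target)) {
      have <- sum(bond_order_equiv(myb))
      if (have < target) g <- mg_add_h(g, i, target - have)
    }
  }
  g
}

# Smallest rings: for every edge on a cycle, the shortest cycle through it.
# A superset of the SSSR that is convenient for peripheral-ring analysis.
#' @noRd
mol_rings <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(list())
  gi <- mg_igraph(g)
  bridge <- as.integer(igraph::bridges(gi))
  ringe <- setdiff(seq_len(nb), bridge)
  seen <- character(0)
  out <- list()
  for (e in ringe) {
    u <- g$bonds$a1[e]; v <- g$bonds$a2[e]
    gi2 <- igraph::delete_edges(gi, e)
    sp <- suppressWarnings(igraph::shortest_paths(gi2, from = u, to = v)$vpath[[1]])
    if (!length(sp)) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- ring
    }
  }
  out
}

# Bond row indices lying inside a ring (consecutive ring atoms + closure).
#' @noRd
ring_bond_rows <- function(g, ring) {
  pairs <- cbind(ring, c(ring[-1L], ring[1L]))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bk <- key(g$bonds$a1, g$bonds$a2)
  match(key(pairs[, 1L], pairs[, 2L]), bk)
}

# -- per-session memo caches --------------------------------------------------

.ps_cache <- new.env(parent = emptyenv())

#' @noRd
cache_env <- function(name) {
  if (is.null(.ps_cache[[name]])) .ps_cache[[name]] <- new.env(parent = emptyenv())
  .ps_cache[[name]]
}

#' @noRd
memo <- function(name, key, fn) {
  env <- cache_env(name)
  if (!is.null(env[[key]])) return(env[[key]])
  val <- fn()
  env[[key]] <- val
  val
}
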