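# Post-docking triage: locate the ligand phosphate group in each pose,
# measure distances to named receptor residue atoms (author numbering, chain
# required), apply distance criteria, and rank the survivors.

#' Parse a receptor PDB file
#'
#' Reads all ATOM/HETATM records via bio3d, resolves alternate locations
#' (keep the highest occupancy; ties keep altloc "A", then the first seen)
#' and excludes waters by default.
#'
#' @param path PDB file path.
#' @param exclude_waters Drop residues HOH/WAT/DOD (default `TRUE`).
#' @return A `receptor_structure` data.frame: serial, atom_name,
#'   residue_name, chain_id, residue_number, x, y, z, element.
#' @export
parse_receptor <- function(path, exclude_waters = TRUE) {
  if (!file.exists(path)) ps_stop(sprintf("receptor file not found: %s", path), "ps_error_io")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) ps_stop(sprintf("cannot read PDB %s: %s",
                                                      path, conditionMessage(e)),
                                              "ps_error_parse"))
  a <- pdb$atom
  if (exclude_waters) a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  ps_assert(nrow(a) > 0L, sprintf("no atoms in %s", path), "ps_error_parse")
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  key <- paste(a$chain, a$resno, a$resid, a$elety)
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    occ <- a$o[rows]
    best <- rows[occ == max(occ)]
    if (length(best) > 1L) {
      pref <- best[a$alt[best] == "A"]
      best <- if (length(pref)) pref[1L] else best[1L]
    }
    keep[setdiff(rows, best)] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$elety)
  if (anyDuplicated(key)) {
    ps_stop(sprintf("duplicate atom after altloc resolution: %s",
                    key[duplicated(key)][1L]), "ps_error_parse")
  }
  el <- trimws(a$elesy)
  miss <- is.na(el) | !nzchar(el)
  el[miss] <- toupper(substring(gsub("[0-9']", "", trimws(a$elety[miss])), 1L, 1L))
  out <- data.frame(serial = a$eleno, atom_name = a$elety, residue_name = a$resid,
                    chain_id = a$chain, residue_number = a$resno,
                    x = a$x, y = a$y, z = a$z, element = el,
                    stringsAsFactors = FALSE)
  ps_assert(all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z)),
            "non-finite receptor coordinates", "ps_error_parse")
  rownames(out) <- NULL
  structure(out, class = c("receptor_structure", "data.frame"))
}

#' Address a set of atoms of one receptor residue
#'
#' @param chain_id Chain identifier (required; author chain).
#' @param residue_name Three-letter residue name (e.g. `"ARG"`).
#' @param residue_number Author residue number (e.g. `609`).
#' @param atom_names Non-empty character vector of atom names (e.g.
#'   `c("NH1", "NH2", "NE")`).
#' @return A `residue_atom_spec`.
#' @export
residue_atom_spec <- function(chain_id, residue_name, residue_number, atom_names) {
  ps_assert(length(atom_names) >= 1L && all(nzchar(atom_names)),
            "atom_names must be non-empty")
  structure(list(chain_id = chain_id, residue_name = toupper(residue_name),
                 residue_number = as.integer(residue_number),
                 atom_names = toupper(atom_names)),
            class = "residue_atom_spec")
}

#' @noRd
resolve_target <- function(receptor, spec) {
  rows <- receptor$chain_id == spec$chain_id &
    receptor$residue_number == spec$residue_number &
    toupper(receptor$residue_name) == spec$residue_name &
    toupper(receptor$atom_name) %in% spec$atom_names
  if (!any(rows)) {
    ps_stop(sprintf("residue not found in receptor: %s %s%d atoms %s",
                    spec$chain_id, spec$residue_name, spec$residue_number,
                    paste(spec$atom_names, collapse = "/")),
            "ps_error_residue_not_found")
  }
  as.matrix(receptor[rows, c("x", "y", "z"), drop = FALSE])
}

#' Distance criterion between the ligand phosphate and a receptor target
#'
#' @param target A [residue_atom_spec()].
#' @param max_distance Pass ceiling in Angstrom (pass when the minimum
#'   pairwise distance is `<=` this value, unrounded).
#' @param ligand_atom_selector Which ligand phosphate atoms to measure from:
#'   `"phosphate-any"` (P and its oxygens), `"phosphate-P"`, `"phosphate-O"`.
#' @param name Short label used for report columns (default
#'   `"<RES><number>"`).
#' @return A `distance_criterion`.
#' @export
distance_criterion <- function(target, max_distance,
                               ligand_atom_selector = c("phosphate-any",
                                                        "phosphate-P",
                                                        "phosphate-O"),
                               name = NULL) {
  ps_assert(inherits(target, "residue_atom_spec"), "target must be a residue_atom_spec")
  ps_assert(is.numeric(max_distance) && length(max_distance) == 1L && max_distance > 0,
            "max_distance must be a single positive number")
  ligand_atom_selector <- match.arg(ligand_atom_selector)
  name <- name %||% sprintf("%s%d", target$residue_name, target$residue_number)
  structure(list(target = target, max_distance = max_distance,
                 ligand_atom_selector = ligand_atom_selector, name = name),
            class = "distance_criterion")
}

#' Default phosphate-contact criteria for the STAT3 SH2 pocket
#'
#' Phosphate atoms within 4.0 Angstrom of the Arg609 guanidinium nitrogens
#' (NH1/NH2/NE) and within 4.0 Angstrom of the Lys591 terminal nitrogen (NZ),
#' chain A. 4.0 Angstrom is a standard salt-bridge/hydrogen-bond contact
#' ceiling; both thresholds and atom selections are configuration, not
#' constants.
#'
#' @param max_distance Contact ceiling in Angstrom (default 4.0).
#' @param chain_id Receptor chain (default `"A"`).
#' @return Named list of [distance_criterion()] objects.
#' @export
default_distance_criteria <- function(max_distance = 4.0, chain_id = "A") {
  list(
    ARG609 = distance_criterion(
      residue_atom_spec(chain_id, "ARG", 609, c("NH1", "NH2", "NE")),
      max_distance, "phosphate-any"),
    LYS591 = distance_criterion(
      residue_atom_spec(chain_id, "LYS", 591, "NZ"),
      max_distance, "phosphate-any")
  )
}

#' Locate phosphate groups in a pose model
#'
#' @param atoms A pose-model atom data.frame (`element`, `x`, `y`, `z`).
#' @param covalent_max P-O covalent ceiling in Angstrom (default 1.9).
#' @return A list with one entry per phosphorus: `p_row` (row index of P),
#'   `o_rows` (row indices of oxygens within covalent range).
#' @export
locate_phosphate_atoms <- function(atoms, covalent_max = 1.9) {
  p_rows <- which(atoms$element == "P")
  if (!length(p_rows)) {
    ps_stop("not a phosphorylated ligand: no phosphorus atom in pose",
            "ps_error_no_phosphate")
  }
  o_rows_all <- which(atoms$element == "O")
  lapply(p_rows, function(p) {
    pc <- c(atoms$x[p], atoms$y[p], atoms$z[p])
    d <- vapply(o_rows_all, function(o) {
      sqrt(sum((c(atoms$x[o], atoms$y[o], atoms$z[o]) - pc)^2))
    }, 1)
    list(p_row = p, o_rows = o_rows_all[d <= covalent_max])
  })
}

#' Minimum pairwise Euclidean distance between two coordinate sets
#'
#' @param atom_set_a,atom_set_b Numeric matrices with columns x, y, z (rows
#'   are atoms). Both must be non-empty.
#' @return The minimum distance in Angstrom over the Cartesian product.
#' @examples
#' min_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
#' @export
min_distance <- function(atom_set_a, atom_set_b) {
  atom_set_a <- rbind(atom_set_a); atom_set_b <- rbind(atom_set_b)
  if (!nrow(atom_set_a) || !nrow(atom_set_b)) {
    ps_stop("min_distance requires non-empty coordinate sets", "ps_error_invalid")
  }
  best <- Inf
  for (i in seq_len(nrow(atom_set_a))) {
    for (j in seq_len(nrow(atom_set_b))) {
      d <- sqrt(sum((atom_set_a[i, ] - atom_set_b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

#' @noRd
ligand_selector_rows <- function(groups, selector) {
  switch(selector,
         "phosphate-P" = vapply(groups, `[[`, 1L, "p_row"),
         "phosphate-O" = unlist(lapply(groups, `[[`, "o_rows")),
         "phosphate-any" = unique(c(vapply(groups, `[[`, 1L, "p_row"),
                                    unlist(lapply(groups, `[[`, "o_rows")))))
}

#' Apply distance criteria to docked poses
#'
#' Evaluates every pose set against the criteria. Under
#' `"best-pose-only"` only pose index 1 is evaluated; under `"any-pose"` a
#' ligand passes if any pose satisfies all criteria (poses are evaluated in
#' rank order until the first pass). A ligand without phosphorus fails with a
#' recorded reason and never aborts the batch.
#'
#' @param poses A list of `pose_set` objects (as from [run_docking()]).
#' @param receptor A `receptor_structure` from [parse_receptor()].
#' @param criteria Non-empty list of [distance_criterion()] objects. All
#'   targets are resolved against the receptor before any evaluation;
#'   an unresolvable target is a fatal configuration error.
#' @param pose_policy `"best-pose-only"` or `"any-pose"`.
#' @return A list with `hits` (data.frame: ligand_id, pose_index, score, one
#'   `d_<name>` column per criterion with the measured minimum distance in
#'   Angstrom, `passed`, `reason`), `funnel` (one-stage `funnel_report`:
#'   ligands in vs ligands passing), and `passed_ids`.
#' @export
apply_distance_criteria <- function(poses, receptor, criteria = default_distance_criteria(),
                                    pose_policy = c("best-pose-only", "any-pose")) {
  pose_policy <- match.arg(pose_policy)
  ps_assert(length(criteria) >= 1L, "criteria must be non-empty")
  ps_assert(all(vapply(criteria, inherits, TRUE, "distance_criterion")),
            "criteria must be distance_criterion objects")
  targets <- lapply(criteria, function(cr) resolve_target(receptor, cr$target))
  cnames <- vapply(criteria, `[[`, "", "name")
  ps_assert(!anyDuplicated(cnames), "criterion names must be unique")

  rows <- list()
  passed_ids <- character(0)
  for (ps in poses) {
    stopifnot(inherits(ps, "pose_set"))
    models <- if (pose_policy == "best-pose-only") ps$models[1L] else ps$models
    ligand_passed <- FALSE
    for (m in models) {
      dvec <- rep(NA_real_, length(criteria))
      reason <- ""
      ok <- FALSE
      groups <- tryCatch(locate_phosphate_atoms(m$atoms), error = function(e) e)
      if (inherits(groups, "error")) {
        reason <- conditionMessage(groups)
      } else {
        for (k in seq_along(criteria)) {
          sel <- ligand_selector_rows(groups, criteria[[k]]$ligand_atom_selector)
          if (!length(sel)) { reason <- "no ligand atoms for selector"; break }
          dvec[k] <- min_distance(
            as.matrix(m$atoms[sel, c("x", "y", "z"), drop = FALSE]),
            targets[[k]])
        }
        ok <- !anyNA(dvec) && all(dvec <= vapply(criteria, `[[`, 1, "max_distance"))
      }
      row <- data.frame(ligand_id = ps$ligand_id, pose_index = m$pose_index,
                        score = m$score, stringsAsFactors = FALSE)
      for (k in seq_along(cnames)) row[[paste0("d_", cnames[k])]] <- dvec[k]
      row$passed <- ok
      row$reason <- reason
      rows[[length(rows) + 1L]] <- row
      if (ok) { ligand_passed <- TRUE; break }
    }
    if (ligand_passed) passed_ids <- c(passed_ids, ps$ligand_id)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ligand_id = character(0), pose_index = integer(0),
               score = numeric(0), passed = logical(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  funnel <- funnel_report(data.frame(stage = "distance_triage",
                                     n_in = length(poses),
                                     n_out = length(passed_ids),
                                     stringsAsFactors = FALSE))
  list(hits = hits, funnel = funnel, passed_ids = passed_ids)
}

#' Rank passing hit records
#'
#' Passing ligands sorted by docking score ascending (more negative is
#' better); ties broken by smaller sum of criterion distances, then by
#' ligand id. Stable and total.
#'
#' @param hits The `hits` data.frame from [apply_distance_criteria()].
#' @return The passing rows, ranked, with a leading `rank` column.
#' @export
rank_hits <- function(hits) {
  h <- hits[hits$passed, , drop = FALSE]
  if (!nrow(h)) {
    out <- cbind(rank = integer(0), h)
    rownames(out) <- NULL
    return(out)
  }
  dcols <- grep("^d_", names(h), value = TRUE)
  dsum <- if (length(dcols)) rowSums(h[, dcols, drop = FALSE]) else rep(0, nrow(h))
  ord <- order(h$score, dsum, h$ligand_id)
  out <- cbind(rank = seq_len(nrow(h)), h[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}
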