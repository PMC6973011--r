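# Docking gateway: prepare inputs, invoke a pluggable engine (an external
# command template or a deterministic built-in mock), and collect multi-model
# PDBQT poses. No scoring function or search algorithm is implemented here;
# the mock engine exists to exercise every downstream code path with
# analytically predictable geometry.

#' Docking job specification
#'
#' @param receptor_path Receptor file (PDB or PDBQT).
#' @param box_center,box_size Numeric length-3: search box center and edge
#'   lengths in Angstrom. No defaults — the docking grid is always an
#'   explicit configuration choice.
#' @param engine `"mock"` (deterministic built-in) or `"external-command"`.
#' @param engine_command Command template for the external engine, with
#'   placeholders `{receptor} {ligand} {out} {center_x} {center_y} {center_z}
#'   {size_x} {size_y} {size_z} {seed} {exhaustiveness}`.
#' @param exhaustiveness,seed Engine pass-through parameters.
#' @param n_poses_max Maximum number of poses per ligand.
#' @return A `docking_job_spec`.
#' @export
docking_job_spec <- function(receptor_path, box_center, box_size,
                             engine = c("mock", "external-command"),
                             engine_command = NULL,
                             exhaustiveness = 8L, seed = 42L,
                             n_poses_max = 5L) {
  engine <- match.arg(engine)
  ps_assert(is.numeric(box_center) && length(box_center) == 3L,
            "box_center must be numeric length 3")
  ps_assert(is.numeric(box_size) && length(box_size) == 3L && all(box_size > 0),
            "box_size must be three positive lengths")
  if (engine == "external-command") {
    ps_assert(is.character(engine_command) && nzchar(engine_command),
              "engine_command required for the external engine")
  }
  ps_assert(n_poses_max >= 1L, "n_poses_max must be >= 1")
  structure(list(receptor_path = receptor_path,
                 box_center = as.numeric(box_center),
                 box_size = as.numeric(box_size),
                 engine = engine, engine_command = engine_command,
                 exhaustiveness = as.integer(exhaustiveness),
                 seed = as.integer(seed),
                 n_poses_max = as.integer(n_poses_max)),
            class = "docking_job_spec")
}

# AutoDock atom types and element symbols both appear in PDBQT files.
#' @noRd
pdbqt_element <- function(raw, atom_name) {
  el <- trimws(raw)
  map <- c(A = "C", OA = "O", NA. = "N", SA = "S", HD = "H", HS = "H",
           NX = "N", CL = "Cl", BR = "Br")
  out <- character(length(el))
  for (i in seq_along(el)) {
    e <- el[i]
    if (e == "NA") e <- "NA."
    if (nzchar(e) && e %in% names(map)) {
      out[i] <- map[[e]]
    } else if (nzchar(e)) {
      out[i] <- paste0(toupper(substring(e, 1L, 1L)),
                       tolower(substring(e, 2L)))
    } else {
      nm <- gsub("[0-9']", "", trimws(atom_name[i]))
      two <- toupper(substring(nm, 1L, 2L))
      out[i] <- if (two %in% c("CL", "BR")) {
        paste0(substring(two, 1L, 1L), tolower(substring(two, 2L, 2L)))
      } else {
        toupper(substring(nm, 1L, 1L))
      }
    }
  }
  out
}

#' Parse a (multi-model) PDBQT pose file
#'
#' Understands `MODEL`/`ENDMDL` blocks, `REMARK VINA RESULT:` score lines,
#' and fixed-width `ATOM`/`HETATM` coordinate records. A file without any
#' `MODEL` block is treated as a single model.
#'
#' @param path Pose file path.
#' @param ligand_id Identifier stored on the pose set (default: file stem).
#' @return A `pose_set`: list with `ligand_id`, `models` (each with
#'   `pose_index`, `score`, and an `atoms` data.frame: serial, name, element,
#'   x, y, z), and `source_path`.
#' @export
parse_pose_file <- function(path, ligand_id = NULL) {
  if (!file.exists(path)) ps_stop(sprintf("pose file not found: %s", path), "ps_error_io")
  ligand_id <- ligand_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    blocks <- list(seq_along(lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    ps_assert(length(ends) == length(starts), "unbalanced MODEL/ENDMDL blocks",
              "ps_error_parse")
    blocks <- Map(function(s, e) seq(s, e), starts, ends)
  }
  models <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- lines[blocks[[b]]]
    off <- blocks[[b]][1L] - 1L
    sc_line <- grep("^REMARK VINA RESULT:", bl)
    score <- if (length(sc_line)) {
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", bl[sc_line[1L]])),
                          "[[:space:]]+")[[1L]][1L])
    } else {
      NA_real_
    }
    at <- grep("^(ATOM|HETATM)", bl)
    f <- function(l, a, z) substring(l, a, z)
    xs <- suppressWarnings(as.numeric(f(bl[at], 31L, 38L)))
    ys <- suppressWarnings(as.numeric(f(bl[at], 39L, 46L)))
    zs <- suppressWarnings(as.numeric(f(bl[at], 47L, 54L)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) {
      ps_stop(sprintf("malformed coordinate record at line %d of %s",
                      off + at[bad[1L]], path), "ps_error_parse")
    }
    atoms <- data.frame(
      serial = suppressWarnings(as.integer(f(bl[at], 7L, 11L))),
      name = trimws(f(bl[at], 13L, 16L)),
      element = pdbqt_element(f(bl[at], 77L, 78L), f(bl[at], 13L, 16L)),
      x = xs, y = ys, z = zs,
      stringsAsFactors = FALSE
    )
    models[[b]] <- list(pose_index = b, score = score, atoms = atoms)
  }
  structure(list(ligand_id = ligand_id, models = models, source_path = path),
            class = "pose_set")
}

#' Write a pose set as multi-model PDBQT
#'
#' Inverse of [parse_pose_file()]: coordinates are written with three
#' decimals, so parse -> write -> parse is a fixed point.
#'
#' @param pose_set A `pose_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(pose_set, path) {
  out <- character(0)
  for (m in pose_set$models) {
    out <- c(out, sprintf("MODEL %d", m$pose_index))
    if (!is.na(m$score)) {
      out <- c(out, sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000",
                            m$score))
    }
    a <- m$atoms
    serial <- ifelse(is.na(a$serial), seq_len(nrow(a)), a$serial)
    nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name), a$name)
    out <- c(out, sprintf(
      "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s",
      serial, nm, a$x, a$y, a$z, 0, a$element))
    out <- c(out, "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}

# Deterministic mock pose geometry: the anchor atom (first phosphorus, else
# the first heavy atom) sits at the box center; atoms bonded to the anchor at
# 1.6 A along the axes (so a phosphate keeps covalent-range P-O contacts);
# everything else on a 1.5 A lattice well away from the anchor. Pose k > 1 is
# the same layout translated along +z.
#' @noRd
mock_pose_atoms <- function(g, center, pose_index) {
  n <- nrow(g$atoms)
  anchor <- which(g$atoms$element == "P")[1L]
  if (is.na(anchor)) anchor <- 1L
  nbr_rows <- which(g$bonds$a1 == anchor | g$bonds$a2 == anchor)
  nbrs <- ifelse(g$bonds$a1[nbr_rows] == anchor, g$bonds$a2[nbr_rows],
                 g$bonds$a1[nbr_rows])
  axes <- rbind(c(1.6, 0, 0), c(0, 1.6, 0), c(0, 0, 1.6),
                c(-1.6, 0, 0), c(0, -1.6, 0), c(0, 0, -1.6))
  xyz <- matrix(0, n, 3L)
  k <- 0L
  for (i in seq_len(n)) {
    if (i == anchor) next
    j <- match(i, nbrs)
    if (!is.na(j) && j <= nrow(axes)) {
      xyz[i, ] <- axes[j, ]
    } else {
      xyz[i, ] <- c(3 + 1.5 * (k %% 5L), 3 + 1.5 * ((k %/% 5L) %% 5L),
                    3 + 1.5 * (k %/% 25L))
      k <- k + 1L
    }
  }
  shift <- c(0, 0, 1.0 * (pose_index - 1L))
  xyz <- sweep(xyz, 2L, center + shift, `+`)
  counts <- stats::ave(seq_len(n), g$atoms$element, FUN = seq_along)
  data.frame(serial = seq_len(n),
             name = sprintf("%s%d", g$atoms$element, counts),
             element = g$atoms$element,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

#' @noRd
run_mock_engine <- function(id, smiles, spec, out_path) {
  g <- smiles_to_molgraph(smiles)
  g <- mg_subgraph(g, which(!mg_is_h(g)))  # poses carry heavy atoms only
  n_heavy <- nrow(g$atoms)
  models <- lapply(seq_len(spec$n_poses_max), function(p) {
    list(pose_index = p,
         score = -n_heavy / 10 + 0.1 * (p - 1L),
         atoms = mock_pose_atoms(g, spec$box_center, p))
  })
  ps <- structure(list(ligand_id = id, models = models, source_path = out_path),
                  class = "pose_set")
  write_pose_file(ps, out_path)
  parse_pose_file(out_path, ligand_id = id)
}

#' @noRd
fill_template <- function(template, values) {
  for (nm in names(values)) {
    template <- gsub(paste0("{", nm, "}"), values[[nm]], template, fixed = TRUE)
  }
  template
}

#' Dock a set of ligands
#'
#' Runs the engine named in `spec` for each ligand and collects one pose set
#' per ligand the engine scored. Per-ligand failures are recorded, never
#' fatal; ligand order is preserved in the output.
#'
#' @param ligands A data.frame with `product_id`/`product_smiles` (as from
#'   [phosphorylate_library()]) or `id`/`smiles` columns.
#' @param spec A [docking_job_spec()].
#' @param workdir Directory for pose files and per-ligand logs.
#' @return A list with `pose_sets` (named list of `pose_set`, in ligand
#'   order) and `failures` (data.frame: ligand_id, reason).
#' @export
run_docking <- function(ligands, spec, workdir = tempfile("dock")) {
  ps_assert(inherits(spec, "docking_job_spec"), "spec must be a docking_job_spec")
  if (!file.exists(spec$receptor_path)) {
    ps_stop(sprintf("receptor file not found: %s", spec$receptor_path), "ps_error_io")
  }
  ids <- ligands$product_id %||% ligands$id
  smis <- ligands$product_smiles %||% ligands$smiles
  ps_assert(!is.null(ids) && !is.null(smis),
            "ligands need product_id/product_smiles or id/smiles columns")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  pose_sets <- list()
  failures <- data.frame(ligand_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    out_path <- file.path(workdir, paste0(id, ".pdbqt"))
    res <- tryCatch({
      if (spec$engine == "mock") {
        run_mock_engine(id, smis[i], spec, out_path)
      } else {
        lig_path <- file.path(workdir, paste0(id, ".smi"))
        writeLines(paste(smis[i], id), lig_path)
        cmd <- fill_template(spec$engine_command, list(
          receptor = spec$receptor_path, ligand = lig_path, out = out_path,
          center_x = spec$box_center[1L], center_y = spec$box_center[2L],
          center_z = spec$box_center[3L],
          size_x = spec$box_size[1L], size_y = spec$box_size[2L],
          size_z = spec$box_size[3L],
          seed = spec$seed, exhaustiveness = spec$exhaustiveness))
        status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
        if (status != 0L) {
          ps_stop(sprintf("engine exited with status %d", status), "ps_error_engine")
        }
        if (!file.exists(out_path)) {
          ps_stop("engine produced no output file", "ps_error_engine")
        }
        parse_pose_file(out_path, ligand_id = id)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(ligand_id = id, reason = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      pose_sets[[id]] <- res
    }
  }
  list(pose_sets = pose_sets, failures = failures)
}

#' @export
print.pose_set <- function(x, ...) {
  sc <- vapply(x$models, function(m) m$score, 1)
  cat(sprintf("pose_set '%s': %d models, scores [%s]\n", x$ligand_id,
              length(x$models), paste(format(sc), collapse = ", ")))
  invisible(x)
}
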