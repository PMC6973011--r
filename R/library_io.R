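# Compound library ingestion and normalization.
#
# A compound library is a data.frame (class "compound_library") with one row
# per member: id, canonical SMILES, average molecular weight, phenolic
# hydroxyl count, and a free-text flags column used by the filter stage.
# Entries that fail to parse are skipped and recorded in attr(x, "rejects").

PHENOL_SMARTS <- "[OX2H][c]"

#' @noRd
new_compound_library <- function(df, rejects = NULL) {
  rejects <- rejects %||% data.frame(line = integer(0), id = character(0),
                                     input = character(0), reason = character(0),
                                     stringsAsFactors = FALSE)
  structure(df, rejects = rejects, class = c("compound_library", "data.frame"))
}

#' @noRd
build_records <- function(ids, raw_smiles, lines, phenol_pattern = PHENOL_SMARTS) {
  norm <- normalize_compound(raw_smiles, .error = FALSE)
  ok <- !is.na(norm)
  rejects <- data.frame(line = lines[!ok], id = ids[!ok], input = raw_smiles[!ok],
                        reason = rep("unparseable SMILES", sum(!ok)),
                        stringsAsFactors = FALSE)
  ids <- ids[ok]
  if (anyDuplicated(ids)) {
    warning("duplicated compound ids made unique with make.unique()")
    ids <- make.unique(ids, sep = "_dup")
  }
  smi <- norm[ok]
  df <- data.frame(
    id = ids,
    smiles = smi,
    mw = average_mw(smi),
    n_phenol_oh = smarts_count(smi, phenol_pattern),
    flags = rep("", length(ids)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  new_compound_library(df, rejects)
}

#' Read a compound library from .smi or SDF
#'
#' The `.smi` dialect is one entry per line, whitespace-separated
#' `SMILES id`; a missing id is auto-assigned `row<N>` (1-based entry
#' number). Unparseable entries are skipped, counted, and reported in
#' `attr(x, "rejects")`; they are not fatal unless *no* entry parses.
#'
#' @param path Path to the library file.
#' @param format `"smi"`, `"sdf"`, or `"auto"` (by file extension).
#' @param phenol_pattern SMARTS used to count phenolic hydroxyls per record.
#' @return A `compound_library` data.frame with columns `id`, `smiles`
#'   (canonical, salt-stripped), `mw` (g/mol), `n_phenol_oh`, `flags`, and a
#'   `rejects` attribute (data.frame of skipped entries).
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("Oc1ccccc1 cpd1", "CCO cpd2"), f)
#' lib <- read_compound_library(f)
#' lib$mw
#' @export
read_compound_library <- function(path, format = c("auto", "smi", "sdf"),
                                  phenol_pattern = PHENOL_SMARTS) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ps_stop(sprintf("library file not found: %s", path), "ps_error_io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) ps_stop(sprintf("no entries in %s", path), "ps_error_io")
    toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
    raw <- vapply(toks, `[`, "", 1L)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) > 1L) toks[[i]][2L] else sprintf("row%d", i)
    }, "")
    lib <- build_records(ids, raw, keep, phenol_pattern)
  } else {
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdfs)
    n <- length(sdfs)
    ids <- ChemmineR::sdfid(sdfs)
    ids[is.na(ids) | !nzchar(trimws(ids))] <- sprintf("row%d", which(is.na(ids) | !nzchar(trimws(ids))))
    ids <- trimws(ids)
    raw <- rep(NA_character_, n)
    for (i in which(valid)) {
      txt <- paste(c(ChemmineR::sdf2str(sdfs[[i]]), "$$$$", ""), collapse = "\n")
      smi <- tryCatch(
        sub("[\t ].*$", "", sub("\n.*$", "", ChemmineOB::convertFormat("SDF", "CAN", txt, options = ob_noopts))),
        error = function(e) ""
      )
      if (nzchar(smi)) raw[i] <- smi
    }
    lib <- build_records(ids, raw, seq_len(n), phenol_pattern)
  }
  if (nrow(lib) == 0L) {
    ps_stop(sprintf("no parseable records in %s (%d rejects)", path,
                    nrow(attr(lib, "rejects"))), "ps_error_io")
  }
  lib
}

#' Write a compound library to .smi or SDF
#'
#' @param lib A `compound_library` (or any data.frame with `id` and `smiles`).
#' @param path Output path.
#' @param format `"smi"`, `"sdf"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(lib, path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  }
  if (format == "smi") {
    writeLines(paste(lib$smiles, lib$id), path)
  } else {
    inp <- paste(paste(lib$smiles, lib$id), collapse = "\n")
    sdf <- ChemmineOB::convertFormat("SMI", "SDF", inp)
    writeLines(sdf, path, sep = "")
  }
  invisible(path)
}

#' Write the reject log of a library read as TSV
#'
#' @param lib A `compound_library`.
#' @param path Output TSV path (columns: line, id, input, reason).
#' @return `path`, invisibly.
#' @export
write_reject_log <- function(lib, path) {
  write_tsv(attr(lib, "rejects") %||% data.frame(), path)
}

#' Normalize a SMILES string
#'
#' Keeps the largest covalent fragment (salt/counter-ion stripping; ties are
#' broken by higher molecular weight, then lexicographically smallest
#' canonical SMILES) and returns OpenBabel canonical SMILES. Idempotent.
#'
#' @param smiles Character vector of SMILES.
#' @param .error If `TRUE` (default), unparseable input raises a typed parse
#'   error; otherwise it yields `NA`.
#' @return Character vector of canonical SMILES.
#' @examples
#' normalize_compound("Oc1ccccc1.[Na+].[Cl-]")
#' @export
normalize_compound <- function(smiles, .error = TRUE) {
  can <- canonical_smiles(smiles)
  multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
  for (i in multi) {
    frags <- unique(strsplit(can[i], ".", fixed = TRUE)[[1]])
    fcan <- canonical_smiles(frags)
    if (anyNA(fcan)) { can[i] <- NA_character_; next }
    heavy <- vapply(fcan, function(s) mg_heavy_count(smiles_to_molgraph(s)), 1L)
    mw <- average_mw(fcan)
    ord <- order(-heavy, -mw, fcan)
    can[i] <- fcan[ord[1L]]
  }
  if (.error && anyNA(can)) {
    bad <- smiles[is.na(can)]
    ps_stop(sprintf("unparseable SMILES: %s", paste(utils::head(bad, 5L), collapse = ", ")),
            "ps_error_parse")
  }
  can
}

#' Average molecular weight of a molecule
#'
#' Computed by OpenBabel from standard atomic weights, implicit hydrogens
#' included, in g/mol.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of molecular weights.
#' @examples
#' molecular_weight(c("O", "Oc1ccccc1"))
#' @export
molecular_weight <- function(smiles) {
  mw <- average_mw(smiles)
  if (anyNA(mw)) {
    ps_stop(sprintf("unparseable SMILES: %s",
                    paste(utils::head(smiles[is.na(mw)], 5L), collapse = ", ")),
            "ps_error_parse")
  }
  mw
}

#' Count phenolic hydroxyl groups
#'
#' Number of distinct hydroxyl oxygens matching `pattern` (by default a
#' one-hydrogen oxygen bound to an aromatic carbon).
#'
#' @param smiles Character vector of SMILES.
#' @param phenol_pattern SMARTS pattern for the phenolic hydroxyl oxygen.
#' @return Integer vector of counts.
#' @examples
#' count_phenolic_hydroxyls(c("Oc1ccccc1", "OC1CCCCC1", "Oc1ccc(O)cc1"))
#' @export
count_phenolic_hydroxyls <- function(smiles, phenol_pattern = PHENOL_SMARTS) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    ps_stop(sprintf("unparseable SMILES: %s",
                    paste(utils::head(smiles[is.na(can)], 5L), collapse = ", ")),
            "ps_error_parse")
  }
  smarts_count(can, phenol_pattern)
}

#' @export
print.compound_library <- function(x, ...) {
  rej <- attr(x, "rejects")
  cat(sprintf("compound_library: %d records (%d rejects on read)\n",
              nrow(x), if (is.null(rej)) 0L else nrow(rej)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
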