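# Fragment selection: scaffold -> phenol -> molecular weight -> reactive
# moieties, with full per-compound decision provenance and a funnel report.

#' Default reactive-moiety SMARTS patterns
#'
#' Named electrophile exclusion patterns applied at the reactive stage:
#' aldehyde, Michael acceptor (alpha,beta-unsaturated carbonyl), alkyl/benzyl
#' halide, epoxide, acyl halide, isocyanate, anhydride. All overridable via
#' [filter_config()].
#'
#' @return Named character vector of SMARTS.
#' @export
default_reactive_patterns <- function() {
  c(
    michael_acceptor = "[CX3]=[CX3][CX3]=[OX1]",
    aldehyde         = "[CX3H1](=O)[#6]",
    alkyl_halide     = "[CX4][F,Cl,Br,I]",
    epoxide          = "[OX2r3]1[#6r3][#6r3]1",
    acyl_halide      = "[CX3](=O)[F,Cl,Br,I]",
    isocyanate       = "[NX2]=[CX2]=[OX1]",
    anhydride        = "[CX3](=O)[OX2][CX3](=O)"
  )
}

#' Fragment filter configuration
#'
#' @param mw_max Maximum molecular weight in g/mol; compounds pass when
#'   strictly below this bound (default 500, i.e. MW < 500 passes, MW = 500
#'   fails).
#' @param phenol_pattern SMARTS for the phenolic hydroxyl (default: a
#'   one-hydrogen oxygen bound to an aromatic carbon).
#' @param reactive_patterns Named character vector of SMARTS defining
#'   reactive moieties to exclude; an empty vector disables the stage.
#' @param scaffold_set A [scaffold_set()] of natural-product structural
#'   elements (default [default_scaffold_set()]).
#' @param require_phenol If `FALSE` the phenol stage passes everything.
#' @return A `filter_config` object.
#' @export
filter_config <- function(mw_max = 500,
                          phenol_pattern = PHENOL_SMARTS,
                          reactive_patterns = default_reactive_patterns(),
                          scaffold_set = default_scaffold_set(),
                          require_phenol = TRUE) {
  ps_assert(is.numeric(mw_max) && length(mw_max) == 1L && mw_max > 0,
            "mw_max must be a single positive number")
  validate_smarts(phenol_pattern, "phenol pattern")
  reactive_patterns <- unlist(reactive_patterns) %||% character(0)
  if (length(reactive_patterns)) {
    nm <- names(reactive_patterns)
    ps_assert(!is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm),
              "reactive patterns must have unique names")
    for (i in seq_along(reactive_patterns)) {
      validate_smarts(reactive_patterns[[i]],
                      sprintf("reactive pattern '%s'", nm[i]))
    }
  }
  ps_assert(inherits(scaffold_set, "scaffold_set"), "scaffold_set must be a scaffold_set")
  structure(list(mw_max = mw_max, phenol_pattern = phenol_pattern,
                 reactive_patterns = reactive_patterns,
                 scaffold_set = scaffold_set,
                 require_phenol = isTRUE(require_phenol)),
            class = "filter_config")
}

#' Test molecules for reactive moieties
#'
#' @param smiles Character vector of SMILES.
#' @param patterns Named character vector of SMARTS
#'   (default [default_reactive_patterns()]).
#' @return A data.frame with `reactive` (logical) and `pattern` (name of the
#'   first matching pattern, or `NA`).
#' @examples
#' has_reactive_moiety(c("C=CC=O", "Oc1ccccc1", "ClCc1ccccc1"))
#' @export
has_reactive_moiety <- function(smiles, patterns = default_reactive_patterns()) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    ps_stop(sprintf("unparseable SMILES: %s",
                    paste(utils::head(smiles[is.na(can)], 5L), collapse = ", ")),
            "ps_error_parse")
  }
  n <- length(can)
  reactive <- rep(FALSE, n)
  pattern <- rep(NA_character_, n)
  if (length(patterns) && n) {
    refs <- ob_molrefs(can)
    for (i in seq_len(n)) {
      for (nm in names(patterns)) {
        if (ChemmineOB::smartsSearch_OB(list(refs[[i]]), patterns[[nm]]) > 0) {
          reactive[i] <- TRUE
          pattern[i] <- nm
          break
        }
      }
    }
  }
  data.frame(reactive = reactive, pattern = pattern, stringsAsFactors = FALSE)
}

#' Apply the fragment filters to a compound library
#'
#' Stages are applied in fixed order parse -> scaffold -> phenol -> MW ->
#' reactive. The pass set is the intersection of the per-stage pass sets (so
#' it is independent of stage order); only the failing-stage attribution in
#' the decisions table depends on the order, and uses first failure.
#'
#' @param library A `compound_library` (or data.frame with `id`, `smiles`).
#' @param config A [filter_config()].
#' @return A list with `passed` (the surviving `compound_library`),
#'   `decisions` (data.frame: id, stage, passed, detail — one row for the
#'   first failing stage, or one pass row per stage), and `funnel`
#'   (a `funnel_report`).
#' @export
apply_fragment_filters <- function(library, config = filter_config()) {
  ps_assert(nrow(library) > 0L, "library must not be empty")
  ps_assert(inherits(config, "filter_config"), "config must be a filter_config")
  n <- nrow(library)
  can <- canonical_smiles(library$smiles)
  parse_ok <- !is.na(can)

  scaffold_ok <- rep(FALSE, n); scaffold_detail <- rep(NA_character_, n)
  phenol_ok <- rep(FALSE, n); phenol_detail <- rep(NA_character_, n)
  mw_ok <- rep(FALSE, n); mw_detail <- rep(NA_character_, n)
  react_ok <- rep(FALSE, n); react_detail <- rep(NA_character_, n)

  vi <- which(parse_ok)
  if (length(vi)) {
    # stages are computed once per distinct canonical structure
    uq <- unique(can[vi])
    ui <- match(can[vi], uq)

    set_key <- content_hash(list(config$scaffold_set$matching_mode,
                                 config$scaffold_set$canonical))
    scaf <- lapply(uq, function(s) {
      memo("scafmatch", paste(s, set_key),
           function() matches_scaffold_set(s, config$scaffold_set))
    })
    u_scaf_ok <- vapply(scaf, `[[`, TRUE, "match")
    scaffold_ok[vi] <- u_scaf_ok[ui]
    scaffold_detail[vi] <- ifelse(scaffold_ok[vi],
                                  vapply(scaf, `[[`, "", "name")[ui],
                                  "no scaffold-set match")

    if (config$require_phenol) {
      nph <- smarts_count(uq, config$phenol_pattern)[ui]
      phenol_ok[vi] <- nph >= 1L
      phenol_detail[vi] <- sprintf("%d phenolic hydroxyl(s)", nph)
    } else {
      phenol_ok[vi] <- TRUE
      phenol_detail[vi] <- "phenol requirement disabled"
    }

    mw <- average_mw(uq)[ui]
    mw_ok[vi] <- !is.na(mw) & mw < config$mw_max
    mw_detail[vi] <- sprintf("MW %.2f", mw)

    if (length(config$reactive_patterns)) {
      rx <- has_reactive_moiety(uq, config$reactive_patterns)
      react_ok[vi] <- !rx$reactive[ui]
      react_detail[vi] <- ifelse(rx$reactive[ui], rx$pattern[ui], "clean")
    } else {
      react_ok[vi] <- TRUE
      react_detail[vi] <- "reactive stage disabled"
    }
  }

  stage_ok <- cbind(parse = parse_ok, scaffold = scaffold_ok,
                    phenol = phenol_ok, mw = mw_ok, reactive = react_ok)
  stage_detail <- cbind(parse = ifelse(parse_ok, "parsed", "unparseable SMILES"),
                        scaffold = scaffold_detail, phenol = phenol_detail,
                        mw = mw_detail, reactive = react_detail)
  stages <- colnames(stage_ok)

  pass_all <- rowSums(!stage_ok) == 0L

  # decisions: first failing stage, or one pass row per stage
  dec <- vector("list", n)
  for (i in seq_len(n)) {
    if (pass_all[i]) {
      dec[[i]] <- data.frame(id = library$id[i], stage = stages,
                             passed = TRUE, detail = stage_detail[i, ],
                             stringsAsFactors = FALSE)
    } else {
      k <- which(!stage_ok[i, ])[1L]
      dec[[i]] <- data.frame(id = library$id[i], stage = stages[k],
                             passed = FALSE, detail = stage_detail[i, k],
                             stringsAsFactors = FALSE)
    }
  }
  decisions <- do.call(rbind, dec)
  rownames(decisions) <- NULL

  # funnel: survivors of the stage prefix, in fixed stage order
  alive <- rep(TRUE, n)
  rows <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    n_in <- sum(alive)
    alive <- alive & stage_ok[, k]
    rows[[k]] <- data.frame(stage = stages[k], n_in = n_in, n_out = sum(alive),
                            stringsAsFactors = FALSE)
  }
  funnel <- funnel_report(do.call(rbind, rows))

  passed <- library[pass_all, , drop = FALSE]
  rownames(passed) <- NULL
  passed <- new_compound_library(as.data.frame(passed))
  list(passed = passed, decisions = decisions, funnel = funnel)
}

#' Funnel report
#'
#' An ordered per-stage record of input/output counts, as in a screening
#' campaign funnel. Validates that `n_out <= n_in` at every stage and that
#' consecutive stages chain (`n_in[k+1] == n_out[k]`).
#'
#' @param df A data.frame with columns `stage`, `n_in`, `n_out`.
#' @return A `funnel_report`.
#' @export
funnel_report <- function(df) {
  ps_assert(all(c("stage", "n_in", "n_out") %in% names(df)),
            "funnel needs stage/n_in/n_out columns")
  ps_assert(all(df$n_out <= df$n_in), "funnel stage with n_out > n_in")
  if (nrow(df) > 1L) {
    ps_assert(all(df$n_in[-1L] == df$n_out[-nrow(df)]),
              "funnel stages do not chain")
  }
  rownames(df) <- NULL
  structure(df, class = c("funnel_report", "data.frame"))
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("screening funnel:\n")
  w <- max(nchar(x$stage), 8L)
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-*s %9d -> %9d\n", w, x$stage[i], x$n_in[i], x$n_out[i]))
  }
  invisible(x)
}
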