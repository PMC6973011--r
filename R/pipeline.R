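# End-to-end pipeline: ingest -> fragment filters -> phosphorylation ->
# docking -> distance triage -> ranking, with per-stage checkpoints keyed by
# a content hash of the stage inputs, TSV artifacts, and a six-stage funnel.
# The funnel counts parent compounds at every stage (a parent survives a
# stage when at least one of its phospho products does), so counts are
# monotone even when site enumeration yields several products per parent.

#' Pipeline configuration
#'
#' @param library_path Compound library (.smi or SDF).
#' @param receptor_path Receptor PDB/PDBQT.
#' @param workdir Directory for checkpoints and stage artifacts.
#' @param filter A [filter_config()].
#' @param phospho A [phospho_policy()].
#' @param box_center,box_size Docking box (numeric length 3 each).
#' @param engine,engine_command,n_poses_max Passed to [docking_job_spec()].
#' @param criteria List of [distance_criterion()]
#'   (default [default_distance_criteria()]).
#' @param pose_policy `"best-pose-only"` or `"any-pose"`.
#' @param seed Integer seed forwarded to the docking engine.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(library_path, receptor_path, workdir,
                            filter = filter_config(),
                            phospho = phospho_policy(),
                            box_center = c(0, 0, 0), box_size = c(20, 20, 20),
                            engine = "mock", engine_command = NULL,
                            n_poses_max = 5L,
                            criteria = default_distance_criteria(),
                            pose_policy = "best-pose-only",
                            seed = 1L) {
  ps_assert(is.character(library_path) && nzchar(library_path),
            "library_path is required", "ps_error_config")
  ps_assert(is.character(receptor_path) && nzchar(receptor_path),
            "receptor_path is required", "ps_error_config")
  structure(list(library_path = library_path, receptor_path = receptor_path,
                 workdir = workdir, filter = filter, phospho = phospho,
                 box_center = box_center, box_size = box_size,
                 engine = engine, engine_command = engine_command,
                 n_poses_max = as.integer(n_poses_max),
                 criteria = criteria, pose_policy = pose_policy,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `filter` may set
#' `mw_max`, `require_phenol`, `phenol_pattern`, `reactive_patterns` (named
#' map), and `scaffolds` (named map of SMILES plus optional `matching_mode`);
#' `phospho` may set `mode` and `dedupe_symmetric`; `criteria` is a list of
#' entries with `chain`, `residue_name`, `residue_number`, `atom_names`,
#' `max_distance`, and optional `selector`/`name`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ps_stop(sprintf("config file not found: %s", path), "ps_error_config")
  y <- yaml::read_yaml(path)
  for (k in c("library_path", "receptor_path", "workdir")) {
    if (is.null(y[[k]])) ps_stop(sprintf("config key '%s' missing", k), "ps_error_config")
  }
  fc <- y$filter %||% list()
  sset <- if (!is.null(fc$scaffolds)) {
    scaffold_set(unlist(fc$scaffolds),
                 matching_mode = fc$matching_mode %||% "exact-scaffold")
  } else {
    default_scaffold_set()
  }
  filter <- filter_config(
    mw_max = fc$mw_max %||% 500,
    phenol_pattern = fc$phenol_pattern %||% PHENOL_SMARTS,
    reactive_patterns = if (is.null(fc$reactive_patterns))
      default_reactive_patterns() else unlist(fc$reactive_patterns),
    scaffold_set = sset,
    require_phenol = fc$require_phenol %||% TRUE)
  pp <- y$phospho %||% list()
  phospho <- phospho_policy(mode = pp$mode %||% "enumerate-all-sites",
                            dedupe_symmetric = pp$dedupe_symmetric %||% TRUE)
  criteria <- if (is.null(y$criteria)) default_distance_criteria() else {
    crs <- lapply(y$criteria, function(cr) {
      distance_criterion(
        residue_atom_spec(cr$chain %||% "A", cr$residue_name,
                          cr$residue_number, unlist(cr$atom_names)),
        cr$max_distance, cr$selector %||% "phosphate-any", name = cr$name)
    })
    stats::setNames(crs, vapply(crs, `[[`, "", "name"))
  }
  dk <- y$docking %||% list()
  pipeline_config(
    library_path = y$library_path, receptor_path = y$receptor_path,
    workdir = y$workdir, filter = filter, phospho = phospho,
    box_center = as.numeric(unlist(dk$box_center %||% c(0, 0, 0))),
    box_size = as.numeric(unlist(dk$box_size %||% c(20, 20, 20))),
    engine = dk$engine %||% "mock", engine_command = dk$engine_command,
    n_poses_max = dk$n_poses_max %||% 5L,
    criteria = criteria, pose_policy = y$pose_policy %||% "best-pose-only",
    seed = y$seed %||% 1L)
}

#' @noRd
checkpoint_ok <- function(workdir, stage, hash) {
  f <- file.path(workdir, "checkpoints", paste0(stage, ".ok"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1L], hash)
}

#' @noRd
checkpoint_save <- function(workdir, stage, hash) {
  d <- file.path(workdir, "checkpoints")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  writeLines(hash, file.path(d, paste0(stage, ".ok")))
}

#' Run the full screening pipeline
#'
#' Stages run in order ingest -> fragment_filter -> phosphorylation ->
#' docking -> distance_triage -> ranking. Every stage writes its artifact
#' TSVs under `config$workdir`; with `resume = TRUE` a stage whose input
#' hash matches its checkpoint is reloaded from its artifacts instead of
#' recomputed. A fatal stage error aborts with the funnel so far written to
#' `funnel.tsv`.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse matching checkpoints (default `FALSE`).
#' @param quiet Suppress per-stage log lines.
#' @return A list with `funnel` (six-stage `funnel_report`), `ranked`
#'   (ranked hit table), `hits`, `artifacts` (named file paths).
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  ps_assert(inherits(config, "pipeline_config"), "config must be a pipeline_config",
            "ps_error_config")
  if (!file.exists(config$receptor_path)) {
    ps_stop(sprintf("receptor file not found: %s", config$receptor_path),
            "ps_error_config")
  }
  if (!file.exists(config$library_path)) {
    ps_stop(sprintf("library file not found: %s", config$library_path),
            "ps_error_config")
  }
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, n_in, n_out, skipped = FALSE) {
    if (!quiet) {
      message(sprintf("[phosphoscreen] %-15s n_in=%d n_out=%d%s",
                      stage, n_in, n_out, if (skipped) " (checkpoint)" else ""))
    }
  }
  art <- function(name) file.path(wd, name)
  funnel_rows <- list()
  flush_funnel <- function() {
    df <- do.call(rbind, funnel_rows)
    write_tsv(df, art("funnel.tsv"))
    df
  }
  add_stage <- function(stage, n_in, n_out, skipped = FALSE) {
    funnel_rows[[length(funnel_rows) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out,
                 stringsAsFactors = FALSE)
    flush_funnel()
    log_stage(stage, n_in, n_out, skipped)
  }
  on_error_flush <- function(e) {
    flush_funnel()
    stop(e)
  }

  tryCatch({
    # -- ingest --------------------------------------------------------------
    h <- content_hash(list("ingest", file_hash(config$library_path)))
    lib_path <- art("library.tsv")
    if (resume && checkpoint_ok(wd, "ingest", h) && file.exists(lib_path)) {
      lib <- new_compound_library(read_tsv(lib_path, colClasses = c(id = "character")))
      rej_path <- art("ingest_rejects.tsv")
      n_rejects <- if (file.exists(rej_path)) nrow(read_tsv(rej_path)) else 0L
      skipped <- TRUE
    } else {
      lib <- read_compound_library(config$library_path)
      write_tsv(as.data.frame(lib), lib_path)
      write_reject_log(lib, art("ingest_rejects.tsv"))
      checkpoint_save(wd, "ingest", h)
      n_rejects <- nrow(attr(lib, "rejects"))
      skipped <- FALSE
    }
    add_stage("ingest", nrow(lib) + n_rejects, nrow(lib), skipped)

    # -- fragment filters ----------------------------------------------------
    h <- content_hash(list("filter", file_hash(lib_path),
                           config$filter[c("mw_max", "phenol_pattern",
                                           "reactive_patterns", "require_phenol")],
                           config$filter$scaffold_set$canonical,
                           config$filter$scaffold_set$matching_mode))
    pass_path <- art("filter_passed.tsv")
    if (resume && checkpoint_ok(wd, "fragment_filter", h) && file.exists(pass_path)) {
      passed <- new_compound_library(read_tsv(pass_path, colClasses = c(id = "character")))
      skipped <- TRUE
    } else {
      fres <- apply_fragment_filters(lib, config$filter)
      passed <- fres$passed
      write_tsv(as.data.frame(passed), pass_path)
      write_tsv(fres$decisions, art("filter_decisions.tsv"))
      write_tsv(as.data.frame(fres$funnel), art("filter_funnel.tsv"))
      checkpoint_save(wd, "fragment_filter", h)
      skipped <- FALSE
    }
    add_stage("fragment_filter", nrow(lib), nrow(passed), skipped)

    # -- phosphorylation -----------------------------------------------------
    h <- content_hash(list("phospho", file_hash(pass_path), config$phospho))
    prod_path <- art("products.tsv")
    if (resume && checkpoint_ok(wd, "phosphorylation", h) && file.exists(prod_path)) {
      products <- read_tsv(prod_path, colClasses = c(parent_id = "character",
                                                     product_id = "character"))
      skipped <- TRUE
    } else {
      products <- phosphorylate_library(passed, config$phospho)
      write_tsv(products, prod_path)
      checkpoint_save(wd, "phosphorylation", h)
      skipped <- FALSE
    }
    add_stage("phosphorylation", nrow(passed),
              length(unique(products$parent_id)), skipped)

    # -- docking -------------------------------------------------------------
    spec <- docking_job_spec(config$receptor_path, config$box_center,
                             config$box_size, config$engine,
                             config$engine_command, seed = config$seed,
                             n_poses_max = config$n_poses_max)
    h <- content_hash(list("dock", file_hash(prod_path),
                           spec[setdiff(names(spec), "receptor_path")],
                           file_hash(config$receptor_path)))
    pose_dir <- art("poses")
    manifest_path <- art("dock_manifest.tsv")
    if (resume && checkpoint_ok(wd, "docking", h) && file.exists(manifest_path)) {
      manifest <- read_tsv(manifest_path, colClasses = c(ligand_id = "character"))
      pose_sets <- lapply(seq_len(nrow(manifest)), function(i) {
        parse_pose_file(manifest$path[i], ligand_id = manifest$ligand_id[i])
      })
      names(pose_sets) <- manifest$ligand_id
      skipped <- TRUE
    } else {
      dres <- run_docking(products, spec, workdir = pose_dir)
      pose_sets <- dres$pose_sets
      write_tsv(dres$failures, art("dock_failures.tsv"))
      manifest <- data.frame(
        ligand_id = names(pose_sets),
        path = vapply(pose_sets, `[[`, "", "source_path"),
        stringsAsFactors = FALSE)
      write_tsv(manifest, manifest_path)
      checkpoint_save(wd, "docking", h)
      skipped <- FALSE
    }
    docked_parents <- unique(products$parent_id[products$product_id %in% names(pose_sets)])
    add_stage("docking", length(unique(products$parent_id)),
              length(docked_parents), skipped)

    # -- distance triage -----------------------------------------------------
    receptor <- parse_receptor(config$receptor_path)
    tres <- apply_distance_criteria(pose_sets, receptor, config$criteria,
                                    config$pose_policy)
    write_tsv(tres$hits, art("hits.tsv"))
    passing_parents <- unique(products$parent_id[products$product_id %in% tres$passed_ids])
    add_stage("distance_triage", length(docked_parents), length(passing_parents))

    # -- ranking -------------------------------------------------------------
    ranked <- rank_hits(tres$hits)
    # pose paths relative to the workdir, so runs in different workdirs
    # produce byte-identical tables
    ranked$pose_path <- vapply(ranked$ligand_id, function(id) {
      p <- pose_sets[[id]]$source_path %||% NA_character_
      sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", wd), "/?"), "", p)
    }, "")
    ranked$receptor_path <- config$receptor_path
    write_tsv(ranked, art("ranked_hits.tsv"))
    add_stage("ranking", length(passing_parents), length(passing_parents))

    funnel <- funnel_report(flush_funnel())
    list(funnel = funnel, ranked = ranked, hits = tres$hits,
         artifacts = c(library = lib_path, filter_passed = pass_path,
                       products = prod_path, manifest = manifest_path,
                       hits = art("hits.tsv"), ranked = art("ranked_hits.tsv"),
                       funnel = art("funnel.tsv")))
  }, error = on_error_flush)
}
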