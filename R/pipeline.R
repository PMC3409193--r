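#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end-to-end — simulate (or load), distances,
#' ortholog assignment, neighbor-joining, similarity scan, micro-indel
#' extraction and parsimony, conversion statistics, evidence integration —
#' writing one TSV report per stage plus a MANIFEST, each report headed by
#' a provenance comment (package version, seed, parameters). Deterministic
#' given config + seed. Stages communicate only through their on-disk
#' artifacts and the returned in-memory bundle.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   `seed` (required), `out_dir` (required), and either `preset` (a
#'   [make_family()] preset) or `fasta` + optional `region_map`; optional
#'   parameter blocks `scan` (see [scan_params()]), `sawyer` (see
#'   [sawyer_params()]), `model` (distance model), and `stages` (character
#'   vector subset of the stage names above; default all applicable).
#' @return Invisibly, a list of stage results; reports are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "preset", "fasta", "region_map", "scan",
             "sawyer", "model", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("config needs `seed`")
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "distances", "orthologs", "nj", "simscan",
                  "indels", "geneconv", "integrate")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))

  prov <- function(extra = NULL) {
    c(sprintf("# paralogr %s", as.character(utils::packageVersion("paralogr"))),
      sprintf("# seed: %d", config$seed),
      sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      extra)
  }
  emit <- function(df, name, extra = NULL) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    writeLines(prov(extra), path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
    path
  }

  manifest <- list()
  note <- function(stage, status, path = NA_character_) {
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage,
                                                 status = status, path = path)
  }
  res <- list()
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    tryCatch({
      fn()
      note(stage, "ok")
    }, error = function(e) {
      note(stage, paste0("failed: ", conditionMessage(e)))
      readr::write_tsv(bind_rows(manifest),
                       file.path(config$out_dir, "MANIFEST.tsv"))
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  run_stage("simulate", function() {
    if (!is.null(config$preset)) {
      sim <- make_family(config$preset, seed = config$seed)
      res$msa <<- sim$msa
      res$truth <<- sim$truth
      write_msa(sim$msa, file.path(config$out_dir, "alignment.fasta"))
      if (nrow(sim$truth$conversions)) {
        emit(sim$truth$conversions, "truth_conversions")
      }
    } else if (!is.null(config$fasta)) {
      res$msa <<- read_msa(config$fasta, region_map = config$region_map)
    } else {
      abort("config needs `preset` or `fasta`")
    }
  })
  x <- res$msa
  model <- config$model %||% "tn93cl"

  run_stage("distances", function() {
    res$dm <<- pairwise_distance(x, model = model)
    write_distance_tsv(res$dm, file.path(config$out_dir, "distances.tsv"))
    emit(tidy(res$dm), "distances_long", sprintf("# model: %s", model))
  })
  run_stage("orthologs", function() {
    res$orthologs <<- assign_orthologs(res$dm)
    emit(res$orthologs, "orthologs")
  })
  run_stage("nj", function() {
    res$tree <<- neighbor_joining(res$dm)
    ape::write.tree(res$tree, file.path(config$out_dir, "nj.nwk"))
    note("nj_tree", "ok", "nj.nwk")
  })
  run_stage("simscan", function() {
    sp <- do.call(scan_params, config$scan %||% list())
    res$tracks <<- similarity_scan(x, params = sp)
    res$candidates <<- candidate_regions(res$tracks, sp)
    emit(res$tracks, "similarity_tracks")
    emit(res$candidates, "candidate_regions")
  })
  run_stage("indels", function() {
    res$indels <<- extract_indels(x)
    res$parsimony <<- if (!is.null(res$tree)) {
      fitch_steps(shared_indels(res$indels), res$tree, topology_id = "nj")
    } else NULL
    emit(tidy(res$indels), "indel_matrix")
    if (!is.null(res$parsimony)) emit(glance(res$parsimony), "indel_parsimony")
  })
  run_stage("geneconv", function() {
    sw <- do.call(sawyer_params, config$sawyer %||% list())
    if (is.null(sw$seed)) sw$seed <- config$seed
    groups <- split(x$labels, x$species[x$labels])
    groups <- purrr::keep(groups, ~length(.x) >= 2L)
    res$sawyer <<- purrr::map(groups, ~sawyer_test(x, .x, sw)) |> bind_rows()
    emit(res$sawyer, "sawyer_tests")
  })
  run_stage("integrate", function() {
    coloc <- if (!is.null(res$indels) && !is.null(res$tree)) {
      colocalize_indels(shared_indels(res$indels), res$tree, res$candidates)
    } else NULL
    res$calls <<- integrate_calls(res$candidates, coloc, res$sawyer)
    emit(res$calls, "conversion_calls")
  })

  readr::write_tsv(bind_rows(manifest), file.path(config$out_dir, "MANIFEST.tsv"))
  invisible(res)
}
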