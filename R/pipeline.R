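## End-to-end pipeline orchestration: simulate -> build-library -> scan ->
## reciprocal-validate -> call-orthologs -> presence-absence, with a run
## manifest and deterministic, resumable stage outputs.

#' Pipeline configuration
#'
#' Bundles the simulation configuration (or user-supplied inputs) with the
#' scanning/classification parameters and seeds.
#'
#' @param sim A [sim_config()] (used when no user inputs are given).
#' @param regions Fragment regions tibble; `NULL` means four default regions
#'   spanning the simulated family (a TM1-4-like long N-terminal block, two
#'   mid blocks, and a C-terminal block that excludes the tail).
#' @param e_max Hit acceptance E-value threshold.
#' @param min_len Minimum translated segment length.
#' @param exon_evidence_min Distinct regions required to accept an ortholog.
#' @param symfrac,tau Profile construction parameters.
#' @param n_cal Calibration sequences per profile.
#' @param seed Master seed; stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), regions = NULL, e_max = 1e-5,
                            min_len = 20L, exon_evidence_min = 2L,
                            symfrac = 0.5, tau = 5, n_cal = 200L, seed = 1L) {
  structure(list(sim = sim, regions = regions, e_max = e_max,
                 min_len = as.integer(min_len),
                 exon_evidence_min = as.integer(exon_evidence_min),
                 symfrac = symfrac, tau = tau, n_cal = as.integer(n_cal),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default fragment regions for a simulated family
#'
#' Four nested column intervals mirroring the transmembrane-anchored fragments
#' used to classify receptor exons: a long N-terminal block, two central
#' blocks, and a C-terminal block that stops short of the cytoplasmic tail so
#' the tail-less subfamily is fully covered.
#'
#' @param config A [sim_config()].
#' @return Tibble from [fragment_regions()].
#' @export
default_regions <- function(config) {
  L <- config$root_length
  tail_start <- L - config$tail_len
  fragment_regions(
    name = c("TM1-4", "TM4-5", "TM6", "TM6-7"),
    start_col = c(round(0.05 * L), round(0.40 * L), round(0.60 * L), round(0.75 * L)),
    end_col = c(round(0.40 * L), round(0.60 * L), round(0.75 * L),
                min(round(0.92 * L), tail_start))
  )
}

#' Run the full discovery/classification pipeline
#'
#' Stages, in order: simulate (family + genomes + truth), build-library,
#' scan, reciprocal-validate, call-orthologs, presence-absence, score. Stage
#' outputs are written as plain-text TSV/FASTA/JSON files under `out_dir`
#' together with a run manifest; a rerun with an identical config and seed
#' reproduces identical outputs. With `resume = TRUE`, stages whose outputs
#' already exist are not rerun (their outputs are reloaded where downstream
#' stages need them).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed). `NULL` runs in memory
#'   only.
#' @param resume Skip stages whose outputs already exist (default FALSE).
#' @return List of class `pipeline_result`: `family`, `genome`, `library`,
#'   `hits`, `calls`, `pa`, `metrics`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      proteins = file.path(out_dir, "proteins.fasta"),
      contigs = file.path(out_dir, "contigs.fasta"),
      truth = file.path(out_dir, "truth.tsv"),
      library = file.path(out_dir, "library_manifest.json"),
      hits = file.path(out_dir, "hits.tsv"),
      calls = file.path(out_dir, "calls.tsv"),
      presence = file.path(out_dir, "presence_absence.tsv"),
      events = file.path(out_dir, "events.tsv"),
      manifest = file.path(out_dir, "run_manifest.json"))
  }
  done <- function(p) resume && !is.null(p) && file.exists(p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  family <- stage("simulate", simulate_family(config$sim, seed = seed))
  genome <- stage("simulate", emit_genome(family, seed = seed + 1L))
  if (!is.null(paths) && !done(paths$truth)) {
    write_fasta(tibble(id = family$proteins$gene_id, seq = family$proteins$seq),
                paths$proteins)
    write_fasta(genome$contigs[, c("id", "seq")], paths$contigs)
    write_tsv_out(genome$truth, paths$truth)
  }

  regions <- config$regions %||% default_regions(config$sim)
  library <- stage("build-library",
                   build_library(family$alignment, regions,
                                 decoy_alns = family$decoy_alignments,
                                 symfrac = config$symfrac, tau = config$tau,
                                 n_cal = config$n_cal, seed = seed + 2L))
  if (!is.null(paths) && !done(paths$library)) {
    write_library_manifest(library, paths$library)
  }

  hits <- stage("scan", scan_genome(genome$contigs, library,
                                    e_max = config$e_max,
                                    min_len = config$min_len))
  hits <- stage("classify", classify_hits(hits))
  hits <- stage("reciprocal-validate", reciprocal_validate(hits, library))
  if (!is.null(paths) && !done(paths$hits)) write_tsv_out(hits, paths$hits)

  calls <- stage("call-orthologs",
                 call_orthologs(hits, exon_evidence_min = config$exon_evidence_min))
  if (!is.null(paths) && !done(paths$calls)) write_tsv_out(calls, paths$calls)

  pa <- stage("presence-absence", presence_absence(calls, family$tree))
  if (!is.null(paths) && !done(paths$presence)) {
    write_tsv_out(pa, paths$presence)
    write_tsv_out(pa$events, paths$events)
  }

  metrics <- stage("score", score_recovery(calls, hits, genome, family, pa))

  manifest <- list(
    schema = "famscan/run_manifest", schema_version = 1L,
    package_version = as.character(utils::packageVersion("famscan")),
    command = "run_pipeline",
    seed = seed,
    config = list(
      e_max = config$e_max, min_len = config$min_len,
      exon_evidence_min = config$exon_evidence_min,
      symfrac = config$symfrac, tau = config$tau, n_cal = config$n_cal,
      sim = unclass(config$sim)),
    stages = c("simulate", "build-library", "scan", "classify",
               "reciprocal-validate", "call-orthologs", "presence-absence",
               "score"),
    outputs = if (is.null(paths)) NULL else {
      existing <- purrr::keep(paths[names(paths) != "manifest"], file.exists)
      purrr::map(existing, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    },
    metrics = metrics[c("fragment_accuracy", "call_precision", "call_recall",
                        "pa_accuracy")],
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(paths)) {
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  structure(list(family = family, genome = genome, library = library,
                 hits = hits, calls = calls, pa = pa, metrics = metrics,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d hits -> %d calls (%d accepted); fragment accuracy %.3f, presence/absence accuracy %.3f\n",
              nrow(x$hits), nrow(x$calls), sum(x$calls$status == "accepted"),
              x$metrics$fragment_accuracy, x$metrics$pa_accuracy))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(n_hits = nrow(x$hits), n_calls = nrow(x$calls),
         n_accepted = sum(x$calls$status == "accepted"),
         fragment_accuracy = x$metrics$fragment_accuracy,
         call_precision = x$metrics$call_precision,
         call_recall = x$metrics$call_recall,
         pa_accuracy = x$metrics$pa_accuracy)
}
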