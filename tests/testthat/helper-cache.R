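# Shared fixtures computed once per test run. The full-pipeline result is used
# by several suites (end-to-end recovery, tail-truncation control, pipeline
# structure checks); caching avoids repeating the multi-minute run.

.famscan_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .famscan_test_cache)) {
    assign(key, force(expr), envir = .famscan_test_cache)
  }
  get(key, envir = .famscan_test_cache)
}

cached_pipeline <- function() {
  cached("pipeline", run_pipeline(pipeline_config(seed = 1L)))
}

# A small calibrated profile for scoring tests: 6 related 60-residue rows.
cached_small_profile <- function() {
  cached("small_profile", {
    set.seed(42)
    base <- random_aa_seq(60)
    rows <- vapply(1:6, function(i) {
      ch <- strsplit(base, "")[[1]]
      mut <- sample(60, 12)
      ch[mut] <- sample(famscan:::AMINO_ACIDS, 12, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    h <- build_profile(tibble::tibble(id = paste0("s", 1:6), seq = rows),
                       name = "fix60")
    calibrate(h, n_cal = 200, seed = 5)
  })
}

table1_path <- function() {
  system.file("extdata", "table1_classification.tsv", package = "famscan")
}
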