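# Shared small synthetic dataset, generated once per test run.
# Error-free (error_rate = 0) so truth labels and pipeline categories can be
# compared exactly.

.test_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 101L) {
  synthetic_config(
    seed = seed,
    genome_length = 60000L,
    n_known_precursors = 6L,
    n_novel_precursors = 3L,
    n_decoy_features = c(rRNA = 2L, tRNA = 2L, snRNA = 2L, snoRNA = 2L,
                         scRNA = 2L, srpRNA = 2L, repeat_ = 2L, exon = 2L,
                         intron = 2L),
    library_sizes = c(12000, 12000, 12000),
    de_spec = data.frame(mirna = c(1L, 2L), stage = c(2L, 3L),
                         log2fc = c(2, -2)),
    error_rate = 0,
    abundance_sdlog = 1.0
  )
}

small_dataset <- function() {
  if (is.null(.test_cache$ds)) {
    dir <- file.path(tempdir(), "mirsat-small-ds")
    .test_cache$ds <- simulate_dataset(small_config(), dir)
    .test_cache$dir <- dir
  }
  .test_cache$ds
}

small_dataset_dir <- function() {
  small_dataset()
  .test_cache$dir
}

small_pipeline <- function() {
  if (is.null(.test_cache$res)) {
    dir <- small_dataset_dir()
    .test_cache$res <- suppressWarnings(
      run_pipeline(pipeline_config(dir, outdir = file.path(dir, "report"))))
  }
  .test_cache$res
}

# map a truth source label to the annotation category it should receive
truth_source_category <- function(source) {
  ifelse(grepl("^miRNA:", source), "miRNA",
         ifelse(grepl("^novel:", source), "unann", source))
}
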