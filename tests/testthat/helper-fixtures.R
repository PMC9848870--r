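# Session-cached fixtures: generating a full synthetic genome takes a few
# seconds, so tests share one per seed.

.fixture_env <- new.env(parent = emptyenv())

fixture_genome <- function(seed = 42) {
  key <- paste0("g", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_genome(genome_spec(seed = seed))
  }
  .fixture_env[[key]]
}

fixture_study <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_study_set(genome_spec(seed = seed))
  }
  .fixture_env[[key]]
}
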