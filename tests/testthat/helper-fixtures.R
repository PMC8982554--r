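# Small shared fixtures, built once per test run.

fixture_cfg <- pipeline_config()

# A compact 3-cohort dataset reused by several files (generation is cheap
# but caching keeps the suite honest about determinism too).
fixture_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- simulate_dataset(n_cohorts = 3, n_tumor = 30, n_normal = 30,
                              n_genes = 120, n_enhancers = 60, seed = 42)
    }
    ds
  }
})

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 1e6) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(5000, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
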