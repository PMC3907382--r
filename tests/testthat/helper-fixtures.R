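# Small shared fixtures for unit tests. Everything is generated in code; the
# sizes are deliberately tiny so single tests run in well under a second.

tiny_genome <- function(n_chrom = 2, mb = 2) {
  genome_spec(paste0("chr", seq_len(n_chrom)), rep(mb * 1e6, n_chrom))
}

# A noiseless, artifact-free configuration: the simulated ratios equal the
# planted copy-number signal exactly.
clean_config <- function(seed = 1L) {
  sim_config(noise_sd = 0, dye_bias_a = 1, dye_bias_b = 1,
             gradient_amplitude = 0, seed = seed)
}

# Independent bp-marking oracle for interval-union length on a small genome:
# mark every covered base in a logical vector and count.
bp_marking_union <- function(intervals, chrom_len) {
  total <- 0
  for (cn in unique(intervals$chrom)) {
    marks <- logical(chrom_len)
    cc <- intervals[intervals$chrom == cn, ]
    for (i in seq_len(nrow(cc))) marks[cc$start[i]:cc$end[i]] <- TRUE
    total <- total + sum(marks)
  }
  total
}

# Random call sets on a small genome for merging properties.
random_calls <- function(n, seed, chrom_len = 1e5, n_chrom = 2, n_samples = 3) {
  withr::with_seed(seed, {
    start <- sample.int(chrom_len - 5000, n, replace = TRUE)
    tibble::tibble(
      sample_id = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
      chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
      start = start,
      end = start + sample.int(5000, n, replace = TRUE) - 1,
      status = sample(c("gain", "loss"), n, replace = TRUE),
      mean_log2 = stats::runif(n, 0.5, 1.5) *
        ifelse(sample(c(TRUE, FALSE), n, replace = TRUE), 1, -1),
      n_probes = sample(5:50, n, replace = TRUE)
    )
  })
}
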