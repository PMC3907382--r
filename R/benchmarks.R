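#' Default benchmark genome
#'
#' A scaled-down multi-chromosome genome used by the built-in benchmarks:
#' `n_chrom` chromosomes of `chrom_mb` megabases each. The default 16 x 5 Mb
#' (80 Mb) keeps a 30-CNV load below ~2% of probes, so that quantile
#' normalization — which assumes a mostly neutral array — operates in the same
#' regime as on a real whole-genome design, while staying small enough to
#' simulate many replicates.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_mb Chromosome length in Mb.
#' @return A [genome_spec()] tibble.
#' @export
benchmark_genome <- function(n_chrom = 16, chrom_mb = 5) {
  genome_spec(paste0("chr", seq_len(n_chrom)), rep(chrom_mb * 1e6, n_chrom))
}

#' Recovery benchmark: sensitivity and precision against planted CNVs
#'
#' Simulates `n_reps` independent genomes (30 planted CNVs each by default,
#' per-channel noise sd 0.15, dye bias and spatial gradient on), runs the full
#' pipeline — spatial correction, q-spline normalization, segmentation,
#' calling — and scores the calls against the planted truth with
#' reciprocal-50%-overlap matching ([match_truth()]). Sensitivity is pooled
#' over "callable" truths (>= `min_probes` covering probes and expected
#' |log2 ratio| >= `threshold`); precision is pooled over all calls.
#'
#' Setting `spatial = FALSE, normalize = FALSE` scores the same pipeline on
#' raw ratios, quantifying what the preprocessing stages buy.
#'
#' @param n_reps Number of simulated genomes.
#' @param base_seed Integer; replicate r uses seeds `base_seed + r`,
#'   `base_seed + 1000 + r`, `base_seed + 2000 + r` for design, truth and
#'   hybridization.
#' @param genome Benchmark genome (default [benchmark_genome()]).
#' @param n_cnvs Planted CNVs per genome.
#' @param noise_sd,dye_bias_a,dye_bias_b,gradient_amplitude Simulation
#'   settings (see [sim_config()]).
#' @param spatial,normalize Preprocessing switches (see [preprocess_array()]).
#' @param threshold,min_probes Calling thresholds (see [call_cnvs()]).
#' @return A list: `sensitivity`, `precision` (pooled), and `per_rep`, a
#'   tibble with one row per replicate (`rep`, `n_callable_truth`,
#'   `n_truth_recovered`, `n_calls`, `n_calls_matched`, `sensitivity`,
#'   `precision`).
#' @export
recovery_benchmark <- function(n_reps = 20, base_seed = 1,
                               genome = benchmark_genome(), n_cnvs = 30,
                               noise_sd = 0.15, dye_bias_a = 1.2,
                               dye_bias_b = 0.95, gradient_amplitude = 0.3,
                               spatial = TRUE, normalize = TRUE,
                               threshold = 0.5, min_probes = 5) {
  per_rep <- purrr::map(seq_len(n_reps), function(r) {
    design <- design_probes(genome, seed = base_seed + r)
    truth <- plant_cnvs(genome, n_cnvs, seed = base_seed + 1000 + r)
    cfg <- sim_config(noise_sd = noise_sd, dye_bias_a = dye_bias_a,
                      dye_bias_b = dye_bias_b,
                      gradient_amplitude = gradient_amplitude,
                      seed = base_seed + 2000 + r)
    intens <- simulate_array(design, truth, cfg)
    track <- preprocess_array(intens, design, spatial = spatial,
                              normalize = normalize)
    seg <- segment_track(track, design)
    calls <- call_cnvs(seg, sample_id = paste0("rep", r),
                       threshold = threshold, min_probes = min_probes)
    m <- match_truth(calls, truth, design, threshold = threshold,
                     min_probes = min_probes)
    tibble(
      rep = r,
      n_callable_truth = m$n_callable_truth,
      n_truth_recovered = m$n_truth_recovered,
      n_calls = m$n_calls,
      n_calls_matched = m$n_calls_matched,
      sensitivity = m$sensitivity,
      precision = m$precision
    )
  }) |> dplyr::bind_rows()
  list(
    sensitivity = sum(per_rep$n_truth_recovered) / sum(per_rep$n_callable_truth),
    precision = sum(per_rep$n_calls_matched) / sum(per_rep$n_calls),
    per_rep = per_rep
  )
}

#' Self-self false-positive benchmark
#'
#' Simulates `n_reps` self-self hybridizations (same DNA in both channels, so
#' any call is a false positive), runs the full pipeline at the given
#' thresholds, and returns the per-replicate call counts. With the stringent
#' default retention rule the expected count is 0 in every replicate.
#'
#' @inheritParams recovery_benchmark
#' @param genome Benchmark genome; the default is smaller than the recovery
#'   genome because the statistic is a count, not a rate.
#' @return Integer vector of length `n_reps`: retained CNV calls per
#'   replicate.
#' @export
self_self_benchmark <- function(n_reps = 10, base_seed = 1,
                                genome = benchmark_genome(n_chrom = 4,
                                                          chrom_mb = 2.5),
                                noise_sd = 0.15, threshold = 0.5,
                                min_probes = 5) {
  vapply(seq_len(n_reps), function(r) {
    design <- design_probes(genome, seed = base_seed + r)
    cfg <- sim_config(noise_sd = noise_sd, seed = base_seed + 5000 + r)
    ss <- simulate_self_self(design, cfg)
    as.integer(false_positive_check(ss, design, threshold = threshold,
                                    min_probes = min_probes))
  }, integer(1))
}
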