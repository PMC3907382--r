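#' Assemble a pipeline run configuration
#'
#' Bundles every tunable of the simulate-to-summary pipeline. The calling
#' defaults are the stringent aCGH retention rule (`|mean log2 ratio| >= 0.5`
#' over at least 5 consecutive probes). Configurations round-trip as JSON via
#' [read_run_config()] / [write_run_config()].
#'
#' @param genome A [genome_spec()] tibble (or a list/data frame coercible to
#'   one).
#' @param samples Character vector of test-sample ids to simulate.
#' @param n_cnvs_per_sample CNVs planted per simulated sample.
#' @param size_range,copy_choices Passed to [plant_cnvs()].
#' @param mean_spacing,probe_length,jitter_fraction Passed to
#'   [design_probes()].
#' @param baseline_intensity,noise_sd,dye_bias_a,dye_bias_b,gradient_amplitude
#'   Passed to [sim_config()].
#' @param span,n_anchors Preprocessing tunables.
#' @param k_max_per_mb,penalty_lambda Segmentation tunables.
#' @param threshold,min_probes Calling tunables.
#' @param qpcr_gain_thr,qpcr_loss_thr qPCR status thresholds.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param out_dir Output directory for [run_cnv_pipeline()].
#' @return A list of class `cgh_run_config`.
#' @export
run_config <- function(genome, samples = paste0("sample", 1:5),
                       n_cnvs_per_sample = 30, size_range = c(6100, 570000),
                       copy_choices = c(0L, 1L, 3L, 4L), mean_spacing = 1650,
                       probe_length = 60, jitter_fraction = 0.2,
                       baseline_intensity = 1000, noise_sd = 0.15,
                       dye_bias_a = 1.2, dye_bias_b = 0.95,
                       gradient_amplitude = 0.3, span = 0.3, n_anchors = 100,
                       k_max_per_mb = 10, penalty_lambda = NULL,
                       threshold = 0.5, min_probes = 5, qpcr_gain_thr = 1.4,
                       qpcr_loss_thr = 0.6, seed = 1L, out_dir = ".") {
  genome <- genome_spec(genome$chrom, genome$length)
  structure(
    list(genome = genome, samples = samples,
         n_cnvs_per_sample = n_cnvs_per_sample, size_range = size_range,
         copy_choices = as.integer(copy_choices), mean_spacing = mean_spacing,
         probe_length = probe_length, jitter_fraction = jitter_fraction,
         baseline_intensity = baseline_intensity, noise_sd = noise_sd,
         dye_bias_a = dye_bias_a, dye_bias_b = dye_bias_b,
         gradient_amplitude = gradient_amplitude, span = span,
         n_anchors = n_anchors, k_max_per_mb = k_max_per_mb,
         penalty_lambda = penalty_lambda, threshold = threshold,
         min_probes = min_probes, qpcr_gain_thr = qpcr_gain_thr,
         qpcr_loss_thr = qpcr_loss_thr, seed = as.integer(seed),
         out_dir = out_dir),
    class = "cgh_run_config"
  )
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "cgh_run_config"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$genome <- genome_spec(raw$genome$chrom, raw$genome$length)
  do.call(run_config, raw[setdiff(names(raw), character(0))])
}

log_line <- function(con, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n", file = con,
      append = TRUE)
}

#' Run the full simulate-to-summary pipeline
#'
#' Executes, per sample: CNV planting, hybridization simulation, spatial
#' correction, q-spline normalization, segmentation, CNV calling; then merges
#' calls across samples into CNVRs and writes the population summaries. Every
#' parameter and derived seed is recorded in a plain-text log, and all
#' randomness flows from the config seed, so two runs with the same config are
#' identical.
#'
#' Outputs written under `config$out_dir`: the probe design, per-sample truth
#' and call TSVs, a combined call TSV and BED, the CNVR TSV and BED, and the
#' chromosome-, status- and size-summary TSVs.
#'
#' @param config A [run_config()], or the path to its JSON file.
#' @param annotation Optional gene annotation tibble for gene counts.
#' @return Invisibly, a list with `design`, `truth` (per sample), `calls`,
#'   `cnvrs`, `chrom_summary`, `status_summary`, `size_bins`, and the output
#'   paths.
#' @export
run_cnv_pipeline <- function(config, annotation = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cgh_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  unlink(log_path)
  scalars <- config[!names(config) %in% c("genome", "samples")]
  log_line(log_path, "run-all started")
  log_line(log_path, "samples:", paste(config$samples, collapse = ", "))
  for (nm in names(scalars)) {
    log_line(log_path, "param", nm, "=",
             if (is.null(scalars[[nm]])) "NULL" else
               paste(scalars[[nm]], collapse = ","))
  }

  design <- design_probes(config$genome, mean_spacing = config$mean_spacing,
                          probe_length = config$probe_length,
                          jitter_fraction = config$jitter_fraction,
                          seed = config$seed)
  write_design_tsv(design, file.path(config$out_dir, "design.tsv"))
  log_line(log_path, "designed", nrow(design), "probes (seed", config$seed, ")")

  truth <- list()
  calls <- list()
  for (i in seq_along(config$samples)) {
    sid <- config$samples[i]
    sample_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    log_line(log_path, "sample", sid, "seed", sample_seed)
    tr <- plant_cnvs(config$genome, config$n_cnvs_per_sample,
                     size_range = config$size_range,
                     copy_choices = config$copy_choices, seed = sample_seed)
    truth[[sid]] <- tr
    write_truth_tsv(tr, file.path(config$out_dir, paste0(sid, "_truth.tsv")))
    cfg <- sim_config(baseline_intensity = config$baseline_intensity,
                      noise_sd = config$noise_sd,
                      dye_bias_a = config$dye_bias_a,
                      dye_bias_b = config$dye_bias_b,
                      gradient_amplitude = config$gradient_amplitude,
                      seed = sample_seed + 1L)
    intens <- simulate_array(design, tr, cfg)
    track <- preprocess_array(intens, design, span = config$span,
                              n_anchors = config$n_anchors)
    seg <- segment_track(track, design, k_max_per_mb = config$k_max_per_mb,
                         penalty_lambda = config$penalty_lambda)
    cl <- call_cnvs(seg, sample_id = sid, threshold = config$threshold,
                    min_probes = config$min_probes)
    log_line(log_path, "sample", sid, ":", nrow(cl), "calls (threshold",
             config$threshold, ", min_probes", config$min_probes, ")")
    calls[[sid]] <- cl
  }
  all_calls <- dplyr::bind_rows(calls)
  write_calls_tsv(all_calls, file.path(config$out_dir, "cnv_calls.tsv"))
  if (nrow(all_calls) > 0) {
    write_bed(all_calls, file.path(config$out_dir, "cnv_calls.bed"))
  }

  cnvrs <- merge_to_cnvrs(all_calls)
  readr::write_tsv(cnvrs |> select(-"samples", -"members"),
                   file.path(config$out_dir, "cnvrs.tsv"))
  if (nrow(cnvrs) > 0) write_bed(cnvrs, file.path(config$out_dir, "cnvrs.bed"))
  log_line(log_path, "merged", nrow(all_calls), "calls into", nrow(cnvrs),
           "CNVRs")

  chrom_sum <- chromosome_summary(cnvrs, config$genome, annotation)
  stat_sum <- status_summary(cnvrs)
  bins <- size_bins(cnvrs)
  readr::write_tsv(chrom_sum, file.path(config$out_dir, "chromosome_summary.tsv"))
  readr::write_tsv(stat_sum, file.path(config$out_dir, "status_summary.tsv"))
  readr::write_tsv(bins, file.path(config$out_dir, "size_bins.tsv"))
  log_line(log_path, "run-all finished")

  invisible(list(design = design, truth = truth, calls = all_calls,
                 cnvrs = cnvrs, chrom_summary = chrom_sum,
                 status_summary = stat_sum, size_bins = bins,
                 out_dir = config$out_dir, log = log_path))
}

#' Match CNV calls against a planted truth set
#'
#' Benchmarks recovery with the reciprocal-overlap convention: a truth CNV and
#' a call match when each covers at least `min_recip` of the other.
#' Sensitivity is computed over "callable" truth CNVs — those covered by at
#' least `min_probes` probe midpoints and with `|log2(copies/2)| >=
#' threshold`, the only ones the retention rule can keep — and precision over
#' all calls.
#'
#' @param calls Calls for one sample.
#' @param truth The sample's planted CNVs.
#' @param design The probe design (to count covering probes).
#' @param min_recip Reciprocal overlap fraction (default 0.5).
#' @param threshold,min_probes The calling thresholds used.
#' @return A list: `sensitivity`, `precision`, `n_callable_truth`, `n_calls`,
#'   `n_truth_recovered`, `n_calls_matched`.
#' @export
match_truth <- function(calls, truth, design, min_recip = 0.5,
                        threshold = 0.5, min_probes = 5) {
  mid <- floor((design$start + design$end) / 2)
  callable <- truth |>
    mutate(
      n_probes_in = purrr::pmap_int(
        list(.data$chrom, .data$start, .data$end),
        function(cn, s, e) sum(design$chrom == cn & mid >= s & mid <= e)
      ),
      expected_lr = log2(pmax(.data$copies, 0.25) / 2)
    ) |>
    filter(.data$n_probes_in >= min_probes, abs(.data$expected_lr) >= threshold)

  recip_match <- function(ts, te, cs, ce) {
    ov <- pmin(te, ce) - pmax(ts, cs) + 1
    ov >= min_recip * (te - ts + 1) & ov >= min_recip * (ce - cs + 1)
  }
  truth_hit <- purrr::pmap_lgl(
    list(callable$chrom, callable$start, callable$end),
    function(cn, s, e) {
      cc <- calls[calls$chrom == cn, ]
      nrow(cc) > 0 && any(recip_match(s, e, cc$start, cc$end))
    }
  )
  # Precision is scored against the full truth set: a call recovering a
  # planted CNV that misses the callability filter is still a true positive.
  call_hit <- purrr::pmap_lgl(
    list(calls$chrom, calls$start, calls$end),
    function(cn, s, e) {
      tt <- truth[truth$chrom == cn, ]
      nrow(tt) > 0 && any(recip_match(tt$start, tt$end, s, e))
    }
  )
  list(
    sensitivity = if (nrow(callable) > 0) mean(truth_hit) else NA_real_,
    precision = if (nrow(calls) > 0) mean(call_hit) else NA_real_,
    n_callable_truth = nrow(callable),
    n_calls = nrow(calls),
    n_truth_recovered = sum(truth_hit),
    n_calls_matched = sum(call_hit)
  )
}
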