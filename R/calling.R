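#' Classify a segment mean as gain, loss, or unchanged
#'
#' Gain when `mean_log2 >= threshold`, loss when `mean_log2 <= -threshold`,
#' otherwise unchanged. The boundary is inclusive: a segment mean of exactly
#' +/- 0.5 at the default threshold is called.
#'
#' @param mean_log2 Numeric vector of segment mean log2 ratios (finite).
#' @param threshold Positive calling threshold (default 0.5).
#' @return Character vector: `"gain"`, `"loss"`, or `"unchanged"`.
#' @export
classify_segment <- function(mean_log2, threshold = 0.5) {
  if (threshold <= 0) abort_bad_arg("threshold must be positive")
  if (any(!is.finite(mean_log2))) abort_bad_arg("mean_log2 must be finite")
  dplyr::case_when(
    mean_log2 >= threshold ~ "gain",
    mean_log2 <= -threshold ~ "loss",
    TRUE ~ "unchanged"
  )
}

#' Call CNVs from a segmentation
#'
#' Retains exactly the segments passing both filters — `|mean_log2| >=
#' threshold` and at least `min_probes` consecutive probes — and labels them
#' gain or loss. The defaults (0.5, 5) are the standard stringent aCGH
#' retention rule.
#'
#' @param segmentation A `cgh_segmentation` from [segment_track()], or a
#'   segments tibble with columns `chrom`, `start`, `end`, `n_probes`,
#'   `mean_log2` (e.g. re-imported from disk).
#' @param sample_id Sample identifier attached to every call.
#' @param threshold Calling threshold on `|mean_log2|`.
#' @param min_probes Minimum number of consecutive probes in a segment.
#' @return A tibble of calls: `sample_id`, `chrom`, `start`, `end` (1-based
#'   inclusive bp), `status`, `mean_log2`, `n_probes`, sorted by
#'   `(chrom, start)`.
#' @export
call_cnvs <- function(segmentation, sample_id, threshold = 0.5, min_probes = 5) {
  segs <- if (inherits(segmentation, "cgh_segmentation")) {
    segmentation$segments
  } else {
    segmentation
  }
  req <- c("chrom", "start", "end", "n_probes", "mean_log2")
  if (!all(req %in% names(segs))) {
    abort_bad_arg("segments need columns chrom, start, end, n_probes, mean_log2")
  }
  segs |>
    filter(abs(.data$mean_log2) >= threshold, .data$n_probes >= min_probes) |>
    mutate(sample_id = sample_id,
           status = classify_segment(.data$mean_log2, threshold)) |>
    select("sample_id", "chrom", "start", "end", "status", "mean_log2",
           "n_probes") |>
    arrange(.data$chrom, .data$start)
}

#' Count CNV calls produced by a self-self hybridization
#'
#' Runs the full chain — spatial correction, q-spline normalization, log2
#' track, segmentation, calling — on a self-self array and returns the number
#' of retained calls. Since both channels carry the same DNA, every call is a
#' false positive; at the default stringent thresholds the expected count
#' is 0.
#'
#' @param self_self Intensities from [simulate_self_self()] (or any array
#'   with no true copy-number differences).
#' @param design The probe design.
#' @param span,n_anchors Preprocessing parameters (see [preprocess_array()]).
#' @param k_max_per_mb,penalty_lambda Segmentation parameters (see
#'   [segment_track()]).
#' @param threshold,min_probes Calling parameters (see [call_cnvs()]).
#' @return Integer: the number of retained CNV calls.
#' @export
false_positive_check <- function(self_self, design, span = 0.3,
                                 n_anchors = 100, k_max_per_mb = 10,
                                 penalty_lambda = NULL, threshold = 0.5,
                                 min_probes = 5) {
  track <- preprocess_array(self_self, design, span = span,
                            n_anchors = n_anchors)
  seg <- segment_track(track, design, k_max_per_mb = k_max_per_mb,
                       penalty_lambda = penalty_lambda)
  nrow(call_cnvs(seg, sample_id = "self_self", threshold = threshold,
                 min_probes = min_probes))
}
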