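#' Average a Ct triplicate
#'
#' qPCR crossing-threshold (Ct) values are measured in triplicate; the working
#' Ct is their arithmetic mean. Triplicates whose range exceeds `qc_range`
#' cycles are averaged anyway but flagged with a warning, since a spread that
#' wide usually indicates a pipetting or amplification problem.
#'
#' @param replicates Numeric vector of exactly 3 finite, positive Ct values.
#' @param qc_range Maximum acceptable within-triplicate range in cycles.
#' @return The mean Ct (scalar).
#' @export
mean_ct <- function(replicates, qc_range = 0.5) {
  if (length(replicates) != 3) abort_bad_arg("Ct triplicate must have exactly 3 values")
  if (any(!is.finite(replicates)) || any(replicates <= 0)) {
    abort_bad_arg("Ct values must be finite and positive")
  }
  if (diff(range(replicates)) > qc_range) {
    warning("Ct triplicate range ", signif(diff(range(replicates)), 3),
            " exceeds ", qc_range, " cycles", call. = FALSE)
  }
  mean(replicates)
}

#' Bundle one sample x assay qPCR measurement
#'
#' @param sample_id,assay_id Identifiers; the assay is the primer pair
#'   targeting one CNVR.
#' @param ct_target Three replicate Ct values for the target primer pair.
#' @param ct_refgene Three replicate Ct values for the reference-gene primer
#'   pair (e.g. GAPDH) on the same sample.
#' @return A list of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample_id, assay_id, ct_target, ct_refgene) {
  if (length(ct_target) != 3 || length(ct_refgene) != 3) {
    abort_bad_arg("ct_target and ct_refgene must each hold 3 replicates")
  }
  structure(list(sample_id = sample_id, assay_id = assay_id,
                 ct_target = as.numeric(ct_target),
                 ct_refgene = as.numeric(ct_refgene)),
            class = "qpcr_measurement")
}

#' Relative copy number by the 2^-ddCt method
#'
#' Computes `dCt = mean_ct(target) - mean_ct(refgene)` for the test sample and
#' for the calibrator (the reference individual), then
#' `ddCt = dCt_test - dCt_cal` and `rcn = 2^-ddCt`. An rcn of 1 means the same
#' relative copy number as the calibrator; each halving of ddCt doubles rcn.
#' Status is gain when `rcn >= gain_thr`, loss when `rcn <= loss_thr`, else
#' unchanged; the defaults (1.4, 0.6) sit between diploid (1.0) and a
#' single-copy change (1.5 / 0.5) with margin for assay noise.
#'
#' @param test,calibrator [qpcr_measurement()] objects for the same assay.
#' @param gain_thr,loss_thr Status thresholds on rcn.
#' @param qc_range Passed to [mean_ct()].
#' @return A one-row tibble: `sample_id`, `assay_id`, `delta_delta_ct`,
#'   `rcn`, `inferred_status`.
#' @export
ddct_rcn <- function(test, calibrator, gain_thr = 1.4, loss_thr = 0.6,
                     qc_range = 0.5) {
  stopifnot(inherits(test, "qpcr_measurement"),
            inherits(calibrator, "qpcr_measurement"))
  if (!identical(test$assay_id, calibrator$assay_id)) {
    abort_bad_arg(paste0("assay mismatch: test '", test$assay_id,
                         "' vs calibrator '", calibrator$assay_id, "'"))
  }
  d_test <- mean_ct(test$ct_target, qc_range) - mean_ct(test$ct_refgene, qc_range)
  d_cal <- mean_ct(calibrator$ct_target, qc_range) -
    mean_ct(calibrator$ct_refgene, qc_range)
  ddct <- d_test - d_cal
  rcn <- 2^(-ddct)
  tibble(
    sample_id = test$sample_id,
    assay_id = test$assay_id,
    delta_delta_ct = ddct,
    rcn = rcn,
    inferred_status = dplyr::case_when(
      rcn >= gain_thr ~ "gain",
      rcn <= loss_thr ~ "loss",
      TRUE ~ "unchanged"
    )
  )
}

#' Relative copy numbers for a whole Ct table
#'
#' Convenience wrapper mapping [ddct_rcn()] over a long-format Ct table: one
#' row per sample x assay x role with triplicate columns `ct1..ct3`, role
#' `"target"` or `"refgene"`. The calibrator sample must be present for every
#' assay.
#'
#' @param ct_table A tibble with columns `sample_id`, `assay_id`, `role`,
#'   `ct1`, `ct2`, `ct3` (see [read_ct_table()]).
#' @param calibrator_sample The reference individual's `sample_id`.
#' @inheritParams ddct_rcn
#' @return A tibble with one row per non-calibrator sample x assay (see
#'   [ddct_rcn()]).
#' @export
rcn_table <- function(ct_table, calibrator_sample, gain_thr = 1.4,
                      loss_thr = 0.6, qc_range = 0.5) {
  req <- c("sample_id", "assay_id", "role", "ct1", "ct2", "ct3")
  if (!all(req %in% names(ct_table))) {
    abort_bad_arg("ct_table needs columns sample_id, assay_id, role, ct1..ct3")
  }
  get_meas <- function(sid, aid) {
    rows <- ct_table |> filter(.data$sample_id == sid, .data$assay_id == aid)
    tgt <- rows |> filter(.data$role == "target")
    ref <- rows |> filter(.data$role == "refgene")
    if (nrow(tgt) != 1 || nrow(ref) != 1) {
      abort_bad_arg(paste0("sample ", sid, ", assay ", aid,
                           ": need exactly one target and one refgene row"))
    }
    qpcr_measurement(sid, aid,
                     c(tgt$ct1, tgt$ct2, tgt$ct3),
                     c(ref$ct1, ref$ct2, ref$ct3))
  }
  combos <- ct_table |>
    distinct(.data$sample_id, .data$assay_id) |>
    filter(.data$sample_id != calibrator_sample)
  purrr::pmap(combos, function(sample_id, assay_id) {
    ddct_rcn(get_meas(sample_id, assay_id),
             get_meas(calibrator_sample, assay_id),
             gain_thr = gain_thr, loss_thr = loss_thr, qc_range = qc_range)
  }) |> dplyr::bind_rows()
}

#' Concordance between qPCR relative copy numbers and array calls
#'
#' A qPCR row is concordant when its inferred status equals the array status
#' of the same sample at the assay's target region. The array status is that
#' of the sample's call overlapping the region (>= 1 bp); a sample with no
#' overlapping call counts as `unchanged`. If several calls overlap, the one
#' with the largest overlap decides.
#'
#' @param array_calls A tibble of CNV calls across samples.
#' @param rcn A tibble from [rcn_table()] / [ddct_rcn()].
#' @param assay_map A tibble mapping `assay_id` to its target interval:
#'   columns `assay_id`, `chrom`, `start`, `end`.
#' @return The concordant fraction in `[0, 1]`, with the per-row comparison
#'   attached as attribute `detail`.
#' @export
concordance <- function(array_calls, rcn, assay_map) {
  missing_assays <- setdiff(unique(rcn$assay_id), assay_map$assay_id)
  if (length(missing_assays) > 0) {
    abort_bad_arg(paste0("assays missing from assay_map: ",
                         paste(missing_assays, collapse = ", ")))
  }
  array_status <- function(sid, aid) {
    tgt <- assay_map |> filter(.data$assay_id == aid)
    hits <- array_calls |>
      filter(.data$sample_id == sid, .data$chrom == tgt$chrom,
             .data$start <= tgt$end, .data$end >= tgt$start)
    if (nrow(hits) == 0) return("unchanged")
    ov <- pmin(hits$end, tgt$end) - pmax(hits$start, tgt$start) + 1
    hits$status[which.max(ov)]
  }
  detail <- rcn |>
    mutate(
      array_status = purrr::map2_chr(.data$sample_id, .data$assay_id,
                                     array_status),
      concordant = .data$array_status == .data$inferred_status
    )
  out <- mean(detail$concordant)
  attr(out, "detail") <- detail
  out
}
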