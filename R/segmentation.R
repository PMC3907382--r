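#' Optimal least-squares segmentation of a numeric sequence
#'
#' Partitions an ordered sequence into contiguous segments so that the total
#' sum of squared deviations from segment means is globally minimal, for every
#' segment count `k = 1..k_max`, via dynamic programming with prefix sums
#' (O(k_max * n^2)). The number of segments is then chosen by minimizing the
#' penalized cost `SSE_k + penalty_lambda * k * log(n)`; ties prefer fewer
#' segments.
#'
#' `penalty_lambda` defaults to twice a robust estimate of the per-probe noise
#' variance, `2 * (mad(diff(x)) / sqrt(2))^2` — the BIC-type cost of the two
#' extra parameters (a level and a breakpoint) each additional segment
#' introduces, scaled by the actual measurement noise. The default becomes 0
#' for a noiseless piecewise-constant input, in which case the smallest `k`
#' attaining zero SSE is chosen.
#'
#' @param values Ordered numeric vector (finite).
#' @param k_max Maximum number of segments to consider (1..n).
#' @param penalty_lambda Non-negative penalty weight; `NULL` for the
#'   MAD-based default.
#' @param k Force the returned segmentation to exactly `k` segments instead of
#'   the penalized choice (the full `sse_by_k` is still computed up to
#'   `k_max`).
#' @return An object of class `cgh_dp_fit`: a list with
#'   `segments` (tibble: `first`, `last` 1-based inclusive indices,
#'   `n_probes`, `mean`), `sse_by_k`, `chosen_k`, `penalty_lambda`, `n`.
#' @examples
#' fit <- dp_segment(c(0, 0, 0, 1, 1, 1), k_max = 3)
#' fit$segments
#' @export
dp_segment <- function(values, k_max, penalty_lambda = NULL, k = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) abort_bad_arg("values must be non-empty")
  if (any(!is.finite(values))) abort_bad_arg("values must be finite")
  if (k_max < 1 || k_max > n) abort_bad_arg("k_max must be between 1 and length(values)")

  if (is.null(penalty_lambda)) {
    penalty_lambda <- if (n >= 3) 2 * (mad(diff(values)) / sqrt(2))^2 else 0
  }
  if (penalty_lambda < 0) abort_bad_arg("penalty_lambda must be >= 0")

  # Centering leaves all SSEs and breakpoints unchanged but keeps the prefix
  # sums of squares well conditioned.
  core <- dp_segment_core(values - mean(values), as.integer(k_max))
  sse_by_k <- core$cost
  if (is.null(k)) {
    pen <- sse_by_k + penalty_lambda * seq_len(k_max) * log(n)
    # ties prefer fewer segments; the tolerance absorbs floating-point dust in
    # the prefix-sum SSEs (a noiseless piecewise-constant input must pick the
    # smallest k reaching zero SSE)
    tol <- 1e-9 * max(sse_by_k[1], 1)
    chosen_k <- which(pen <= min(pen) + tol)[1]
  } else {
    if (k < 1 || k > k_max) abort_bad_arg("k must be between 1 and k_max")
    chosen_k <- as.integer(k)
  }

  seg <- dp_backtrack(core$back, as.integer(chosen_k), n)
  segments <- tibble(
    first = seg[, 1],
    last = seg[, 2],
    n_probes = seg[, 2] - seg[, 1] + 1L,
    mean = vapply(seq_len(nrow(seg)),
                  function(i) mean(values[seg[i, 1]:seg[i, 2]]), numeric(1))
  )
  structure(
    list(segments = segments, sse_by_k = sse_by_k, chosen_k = chosen_k,
         penalty_lambda = penalty_lambda, n = n),
    class = "cgh_dp_fit"
  )
}

#' Exact segmentation by exhaustive enumeration (test oracle)
#'
#' Enumerates every partition of the sequence into `k` contiguous blocks and
#' returns the minimum total within-block SSE. Exponential in `n`; guarded at
#' `n <= 25`. Serves as an independent oracle for [dp_segment()].
#'
#' @param values Ordered numeric vector, length <= 25.
#' @param k Number of segments.
#' @return A list with `cost` and `breakpoints` (indices of the last element
#'   of each segment except the final one; empty for `k = 1`). On ties the
#'   lexicographically smallest breakpoint vector encountered first is kept.
#' @export
brute_force_segment <- function(values, k) {
  values <- as.numeric(values)
  n <- length(values)
  if (n > 25) abort_bad_arg("brute_force_segment is limited to n <= 25")
  if (k < 1 || k > n) abort_bad_arg("k must be between 1 and length(values)")
  block_sse <- function(a, b) {
    x <- values[a:b]
    sum((x - mean(x))^2)
  }
  if (k == 1) {
    return(list(cost = block_sse(1, n), breakpoints = integer(0)))
  }
  combos <- utils::combn(n - 1, k - 1)
  best <- Inf
  best_bp <- NULL
  for (ci in seq_len(ncol(combos))) {
    bp <- combos[, ci]
    bounds <- c(0L, bp, n)
    cost <- 0
    for (s in seq_len(k)) cost <- cost + block_sse(bounds[s] + 1L, bounds[s + 1L])
    if (cost < best) {
      best <- cost
      best_bp <- bp
    }
  }
  list(cost = best, breakpoints = as.integer(best_bp))
}

#' Segment every chromosome of a log2-ratio track
#'
#' Runs [dp_segment()] independently per chromosome. The per-chromosome
#' segment budget is `k_max = min(n, max(1, ceiling(k_max_per_mb * span)))`
#' where `span` is the probe-covered extent of the chromosome in Mb.
#'
#' @param track A log2-ratio track from [to_log2_track()].
#' @param design The probe design the track was computed on (provides the
#'   genomic start/end of each probe).
#' @param k_max_per_mb Segment budget per Mb of probe-covered sequence.
#' @param penalty_lambda Passed to [dp_segment()] (`NULL` = per-chromosome
#'   MAD-based default).
#' @return An object of class `cgh_segmentation`: a list with `segments`
#'   (tibble: `chrom`, `start`, `end` in bp — start of the first probe to end
#'   of the last probe —, `first`, `last`, `n_probes`, `mean_log2`) and
#'   `by_chrom` (one row per chromosome: `chrom`, `n_probes`, `k_max`,
#'   `chosen_k`, `penalty_lambda`, `sse`, with `sse_by_k` as a list column).
#' @export
segment_track <- function(track, design, k_max_per_mb = 10,
                          penalty_lambda = NULL) {
  if (nrow(track) == 0) abort_bad_arg("track is empty")
  pos <- design |> select("probe_id", "start", "end")
  seg_list <- list()
  meta_list <- list()
  for (cn in unique(track$chrom)) {
    tr <- track[track$chrom == cn, ]
    if (nrow(tr) == 0) {
      warning("chromosome ", cn, " has no probes; skipped", call. = FALSE)
      next
    }
    tr <- dplyr::left_join(tr, pos, by = "probe_id")
    span_mb <- (max(tr$end) - min(tr$start) + 1) / 1e6
    k_max <- min(nrow(tr), max(1, ceiling(k_max_per_mb * span_mb)))
    fit <- dp_segment(tr$log2_ratio, k_max = k_max, penalty_lambda = penalty_lambda)
    seg_list[[cn]] <- fit$segments |>
      mutate(
        chrom = cn,
        start = tr$start[.data$first],
        end = tr$end[.data$last]
      ) |>
      select("chrom", "start", "end", "first", "last", "n_probes",
             mean_log2 = "mean")
    meta_list[[cn]] <- tibble(
      chrom = cn, n_probes = nrow(tr), k_max = k_max, chosen_k = fit$chosen_k,
      penalty_lambda = fit$penalty_lambda, sse = fit$sse_by_k[fit$chosen_k],
      sse_by_k = list(fit$sse_by_k)
    )
  }
  if (length(seg_list) == 0) abort_bad_arg("no chromosome could be segmented")
  structure(
    list(segments = dplyr::bind_rows(seg_list),
         by_chrom = dplyr::bind_rows(meta_list)),
    class = "cgh_segmentation"
  )
}

#' @export
print.cgh_dp_fit <- function(x, ...) {
  cat("Least-squares segmentation:", x$n, "points,", x$chosen_k,
      "segments (lambda =", signif(x$penalty_lambda, 3), ")\n")
  print(x$segments)
  invisible(x)
}

#' @export
print.cgh_segmentation <- function(x, ...) {
  cat("Segmented", nrow(x$by_chrom), "chromosome(s),",
      nrow(x$segments), "segments total\n")
  print(x$segments)
  invisible(x)
}
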