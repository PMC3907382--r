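#' LOESS spatial correction of array-position artifacts
#'
#' Hybridization surfaces show smooth position-dependent intensity trends.
#' For each channel independently, a locally weighted linear surface (tricube
#' weights) of log2 intensity over the array grid — `(row, col)` rescaled to
#' the unit square — is fitted and subtracted after removing its own global
#' mean, so each channel's grand mean log2 intensity is preserved exactly.
#'
#' @param intensities An intensity tibble from [simulate_array()] (or read
#'   from disk and joined to a design): columns `probe_id`, `test_intensity`,
#'   `ref_intensity`, `row`, `col`.
#' @param span LOESS span in (0, 1]; fraction of probes in each local fit.
#' @return The intensity tibble with both channels corrected (still positive,
#'   same probe order).
#' @export
spatial_correct <- function(intensities, span = 0.3) {
  if (span <= 0 || span > 1) abort_bad_arg("span must be in (0, 1]")
  n <- nrow(intensities)
  if (n < 50) abort_bad_arg("spatial correction needs >= 50 probes")

  u <- if (max(intensities$row) > 0) intensities$row / max(intensities$row) else rep(0, n)
  v <- if (max(intensities$col) > 0) intensities$col / max(intensities$col) else rep(0, n)

  correct_channel <- function(x) {
    l <- log2(x)
    fit <- tryCatch(
      loess(l ~ u + v, span = span, degree = 1, family = "gaussian",
            normalize = FALSE,
            control = loess.control(surface = "interpolate",
                                    statistics = "approximate",
                                    trace.hat = "approximate")),
      error = function(e) {
        stop("local surface fit failed (", conditionMessage(e),
             "); try a larger span", call. = FALSE)
      }
    )
    f <- fit$fitted
    2^(l - (f - mean(f)))
  }

  intensities |>
    mutate(
      test_intensity = correct_channel(.data$test_intensity),
      ref_intensity = correct_channel(.data$ref_intensity)
    )
}

# Monotone anchor-quantile spline map: inside the anchor range a monotone
# Hermite cubic through (from, to); beyond it, linear continuation. The
# continuation slope comes from a least-squares line through the outer tenth
# of the anchors (at least 5): single-interval slopes of empirical quantiles
# are too noisy to extrapolate through the tails, where the copy-number
# signal sits far outside the anchor range.
quantile_spline_map <- function(from, to) {
  keep <- !duplicated(from)
  from <- from[keep]
  to <- to[keep]
  m <- length(from)
  if (m < 2 || any(diff(from) <= 0) || any(diff(to) <= 0)) {
    return(NULL)
  }
  f <- splinefun(from, to, method = "monoH.FC")
  lo <- from[1]; hi <- from[m]
  k <- min(m, max(5L, ceiling(m / 10)))
  end_slope <- function(idx) {
    if (length(idx) < 2) return(1)
    stats::cov(from[idx], to[idx]) / stats::var(from[idx])
  }
  slope_lo <- max(end_slope(seq_len(k)), 0)
  slope_hi <- max(end_slope(seq(m - k + 1L, m)), 0)
  function(x) {
    y <- f(pmin(pmax(x, lo), hi))
    y[x < lo] <- to[1] + slope_lo * (x[x < lo] - lo)
    y[x > hi] <- to[m] + slope_hi * (x[x > hi] - hi)
    y
  }
}

#' q-spline normalization of the two dye channels
#'
#' Removes dye bias by mapping the channels onto a common intensity
#' distribution. Quantiles of each channel's log2 intensity are taken at
#' `n_anchors` evenly spaced probabilities spanning `anchor_range`, pairing
#' each channel's quantile with the target distribution's quantile at the same
#' probability (see `target`). A monotone cubic spline through the anchor
#' pairs remaps the channel; beyond the anchor range the map continues
#' linearly.
#'
#' The anchors deliberately stop short of the extreme quantiles: in CGH data
#' the distribution tails are where true copy-number signal lives, and bending
#' the map inside them would shrink that signal toward the reference. The
#' anchor range should exclude the expected fraction of aberrant probes per
#' tail; the linear continuation is exact for a power-law (affine in log)
#' dye bias, which is what the tails otherwise carry.
#'
#' True copy-number changes make the two channels' distributions differ for
#' reasons that are not dye bias; feeding those probes into the quantile pairs
#' would warp the map and shrink the very signal being measured. The anchors
#' are therefore estimated from the apparently neutral probes only, and the
#' fitted map is then applied to every probe (the invariant-set idea long used
#' in microarray normalization). Neutrality is judged on the raw log2 ratio
#' smoothed over `mask_smooth` consecutive probes (probes are assumed to
#' arrive in genome order, as [design_probes()] emits them): smoothing makes
#' the mask a property of the genomic region rather than of each probe's own
#' noise. Masking on unsmoothed ratios would preferentially discard probes
#' with large noise deviations, which equalizes the two channels' apparent
#' spreads and flattens exactly the tail slope the map needs. Set
#' `neutral_mask_width = NULL` to estimate from all probes.
#'
#' If a channel is degenerate (constant, so its anchor quantiles are not
#' strictly increasing), the function falls back to median scaling with a
#' warning.
#'
#' @inheritParams spatial_correct
#' @param n_anchors Number of quantile anchors (>= 5).
#' @param anchor_range Probability range covered by the anchors.
#' @param neutral_mask_width Half-width, in log2-ratio units around the median
#'   ratio, of the band of (smoothed) probes used to estimate the map
#'   (`NULL` = all probes).
#' @param mask_smooth Width, in probes, of the running mean applied to the raw
#'   ratio before masking (1 = no smoothing).
#' @param target `"reference"` (default) maps the test channel onto the
#'   reference channel's quantiles and leaves the reference untouched — the
#'   reference genome is diploid by construction, so it is the natural
#'   calibration target and genuine test-channel signal keeps its full
#'   magnitude. `"midpoint"` maps both channels onto the per-probability
#'   midpoint of their log2 quantiles (the geometric mean on the linear
#'   scale), treating the dyes symmetrically.
#' @return The intensity tibble with both channels normalized.
#' @export
qspline_normalize <- function(intensities, n_anchors = 100,
                              anchor_range = c(0.02, 0.98),
                              neutral_mask_width = 0.25, mask_smooth = 5,
                              target = c("reference", "midpoint")) {
  target <- match.arg(target)
  if (n_anchors < 5) abort_bad_arg("n_anchors must be >= 5")
  if (anchor_range[1] <= 0 || anchor_range[2] >= 1 ||
      anchor_range[1] >= anchor_range[2]) {
    abort_bad_arg("anchor_range must satisfy 0 < lo < hi < 1")
  }
  lt <- log2(intensities$test_intensity)
  lr <- log2(intensities$ref_intensity)
  if (any(!is.finite(lt)) || any(!is.finite(lr))) {
    abort_bad_arg("intensities must be positive and finite")
  }

  neutral <- rep(TRUE, length(lt))
  if (!is.null(neutral_mask_width)) {
    ratio0 <- lt - lr - median(lt - lr)
    if (mask_smooth > 1) {
      sm <- stats::filter(ratio0, rep(1 / mask_smooth, mask_smooth), sides = 2)
      ratio0 <- ifelse(is.na(sm), 0, as.numeric(sm))
    }
    neutral <- abs(ratio0) <= neutral_mask_width
    if (sum(neutral) < max(50, n_anchors)) neutral <- rep(TRUE, length(lt))
  }

  probs <- seq(anchor_range[1], anchor_range[2], length.out = n_anchors)
  qt <- unname(quantile(lt[neutral], probs))
  qr <- unname(quantile(lr[neutral], probs))
  tgt <- if (target == "reference") qr else (qt + qr) / 2

  map_t <- quantile_spline_map(qt, tgt)
  map_r <- if (target == "reference") identity else quantile_spline_map(qr, tgt)
  if (is.null(map_t) || is.null(map_r)) {
    warning("degenerate channel quantiles; falling back to median scaling",
            call. = FALSE)
    target_med <- (median(lt) + median(lr)) / 2
    return(intensities |>
             mutate(test_intensity = 2^(lt - median(lt) + target_med),
                    ref_intensity = 2^(lr - median(lr) + target_med)))
  }

  intensities |>
    mutate(test_intensity = 2^map_t(lt), ref_intensity = 2^map_r(lr))
}

#' Convert intensities to an ordered per-chromosome log2-ratio track
#'
#' Computes `log2(test / reference)` per probe and orders probes by genomic
#' midpoint within each chromosome (midpoint = `floor((start + end) / 2)`,
#' 1-based).
#'
#' @inheritParams spatial_correct
#' @param design The probe design the intensities are aligned to.
#' @return A tibble with columns `chrom`, `probe_id`, `midpoint`,
#'   `log2_ratio`, sorted by chromosome (design order) then midpoint.
#' @export
to_log2_track <- function(intensities, design) {
  if (nrow(intensities) != nrow(design) ||
      !identical(intensities$probe_id, design$probe_id)) {
    abort_bad_arg("intensities are not aligned to the design")
  }
  lr <- log2(intensities$test_intensity / intensities$ref_intensity)
  if (any(!is.finite(lr))) abort_bad_arg("non-finite log2 ratios")
  tibble(
    chrom = design$chrom,
    probe_id = design$probe_id,
    midpoint = floor((design$start + design$end) / 2),
    log2_ratio = lr
  ) |>
    mutate(chrom = factor(.data$chrom, levels = unique(design$chrom))) |>
    arrange(.data$chrom, .data$midpoint) |>
    mutate(chrom = as.character(.data$chrom))
}

#' Run the full preprocessing chain
#'
#' Applies, in order, LOESS spatial correction, q-spline normalization, and
#' conversion to a log2-ratio track. The order matters: position artifacts are
#' removed per channel before the channels' distributions are equalized, and
#' ratios are only formed at the end.
#'
#' @inheritParams to_log2_track
#' @param span LOESS span for [spatial_correct()].
#' @param n_anchors,anchor_range Anchor settings for [qspline_normalize()].
#' @param spatial,normalize Logical switches for the two correction steps
#'   (both `TRUE` for normal use; switching them off is intended for benchmark
#'   comparisons).
#' @return A log2-ratio track tibble (see [to_log2_track()]).
#' @export
preprocess_array <- function(intensities, design, span = 0.3, n_anchors = 100,
                             anchor_range = c(0.02, 0.98), spatial = TRUE,
                             normalize = TRUE) {
  x <- intensities
  if (spatial) x <- spatial_correct(x, span = span)
  if (normalize) {
    x <- qspline_normalize(x, n_anchors = n_anchors,
                           anchor_range = anchor_range)
  }
  to_log2_track(x, design)
}
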