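#' Define a genome as an ordered set of chromosomes
#'
#' A genome specification is the coordinate backbone for probe design and CNV
#' planting: an ordered table of chromosome names and lengths in base pairs.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bp (all > 0).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) abort_bad_arg("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort_bad_arg("chromosome lengths must be positive")
  }
  tibble(chrom = chrom, length = length)
}

#' Design a tiling probe layout over a genome
#'
#' Probes of fixed length are laid down chromosome by chromosome with
#' start-to-start spacing drawn uniformly in
#' `mean_spacing * (1 - jitter_fraction)` to `mean_spacing * (1 + jitter_fraction)`.
#' Array grid positions `(row, col)` are assigned row-major over a near-square
#' grid, mimicking the physical layout of a tiling aCGH chip (typical designs
#' tile at ~1650 bp average spacing).
#'
#' All random draws come from a single seeded stream: per chromosome, in
#' genome order, one uniform gap per probe step.
#'
#' @param genome A [genome_spec()] tibble.
#' @param mean_spacing Mean start-to-start probe distance in bp.
#' @param probe_length Probe length in bp; must satisfy
#'   `mean_spacing * (1 - jitter_fraction) > probe_length` so probes never
#'   overlap.
#' @param jitter_fraction Half-width of the relative spacing jitter, in
#'   `[0, 1)`.
#' @param seed Integer seed for the spacing jitter.
#' @return A tibble with columns `probe_id`, `chrom`, `start`, `end`
#'   (1-based inclusive bp) and `row`, `col` (0-based grid indices).
#'   Chromosomes shorter than `mean_spacing` receive no probes and trigger a
#'   warning.
#' @examples
#' g <- genome_spec("chr1", 1650000)
#' d <- design_probes(g, mean_spacing = 1650, jitter_fraction = 0, seed = 1)
#' nrow(d) # 1000
#' @export
design_probes <- function(genome, mean_spacing = 1650, probe_length = 60,
                          jitter_fraction = 0.2, seed = 1L) {
  if (mean_spacing <= probe_length) {
    abort_bad_arg("mean_spacing must exceed probe_length")
  }
  if (jitter_fraction < 0 || jitter_fraction >= 1) {
    abort_bad_arg("jitter_fraction must be in [0, 1)")
  }
  if (mean_spacing * (1 - jitter_fraction) <= probe_length) {
    abort_bad_arg(
      "minimum spacing mean_spacing*(1 - jitter_fraction) must exceed probe_length"
    )
  }
  lo <- mean_spacing * (1 - jitter_fraction)
  hi <- mean_spacing * (1 + jitter_fraction)

  per_chrom <- withr::with_seed(seed, {
    purrr::map2(genome$chrom, genome$length, function(cn, len) {
      if (len < mean_spacing) {
        warning("chromosome ", cn, " is shorter than mean_spacing; no probes placed",
                call. = FALSE)
        return(tibble(chrom = character(), start = numeric()))
      }
      starts <- numeric(ceiling(len / lo) + 1L)
      pos <- 1
      k <- 0L
      while (pos + probe_length - 1 <= len) {
        k <- k + 1L
        starts[k] <- pos
        gap <- if (jitter_fraction == 0) mean_spacing else round(runif(1, lo, hi))
        pos <- pos + gap
      }
      tibble(chrom = cn, start = starts[seq_len(k)])
    })
  })

  design <- dplyr::bind_rows(per_chrom)
  n <- nrow(design)
  side <- ceiling(sqrt(n))
  design |>
    mutate(
      probe_id = sprintf("P%07d", seq_len(n)),
      end = .data$start + probe_length - 1,
      row = (seq_len(n) - 1L) %/% side,
      col = (seq_len(n) - 1L) %% side
    ) |>
    select("probe_id", "chrom", "start", "end", "row", "col")
}

#' Plant non-overlapping copy-number variants in a genome
#'
#' Draws `n_cnvs` ground-truth CNV intervals: chromosome chosen with
#' probability proportional to length, start uniform over the feasible range,
#' copy number sampled from `copy_choices` (the reference is diploid, so 2 is
#' excluded). Intervals are rejected and redrawn if they would overlap an
#' already-placed CNV. Per CNV the draw order is: copy number, then per
#' attempt (chromosome, size, start).
#'
#' The default size range reflects the span reported for horse aCGH CNVs
#' (6.1 kb to 0.57 Mb). CNV sizes in such surveys are strongly right-skewed
#' (mean around 43 kb, median near 15 kb), so the default `size_dist` draws a
#' lognormal with `meanlog = log(15110)`, `sdlog = 1.3`, rejection-truncated
#' to `size_range`; the truncated draw has mean about 42 kb and median about
#' 22 kb (the lower cut-off pulls the median up). `size_dist = "uniform"`
#' draws sizes uniformly over `size_range` instead.
#'
#' @param genome A [genome_spec()] tibble.
#' @param n_cnvs Number of CNVs to place.
#' @param size_range Length-2 numeric, min/max CNV size in bp.
#' @param copy_choices Integer copy numbers (>= 0, never 2) to sample from.
#' @param size_dist `"lognormal"` (default) or `"uniform"`.
#' @param min_gap Minimum distance in bp between planted CNVs. Two CNVs closer
#'   than the probe spacing cannot be told apart by the array, so the default
#'   keeps planted CNVs at least ~12 probe intervals apart, making every
#'   planted event resolvable in principle.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per CNV before giving up.
#' @return A tibble with columns `chrom`, `start`, `end`, `copies`, sorted by
#'   position.
#' @export
plant_cnvs <- function(genome, n_cnvs, size_range = c(6100, 570000),
                       copy_choices = c(0L, 1L, 3L, 4L),
                       size_dist = c("lognormal", "uniform"), min_gap = 20000,
                       seed = 1L, max_tries = 1000L) {
  size_dist <- match.arg(size_dist)
  if (any(copy_choices == 2L)) abort_bad_arg("copy_choices must exclude the diploid value 2")
  if (any(copy_choices < 0L)) abort_bad_arg("copy_choices must be non-negative")
  if (size_range[1] > size_range[2]) abort_bad_arg("size_range must be increasing")
  if (max(size_range) > max(genome$length)) {
    abort_bad_arg("size_range exceeds every chromosome length")
  }
  if (n_cnvs == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  copies = integer()))
  }

  placed <- withr::with_seed(seed, {
    out <- vector("list", n_cnvs)
    by_chrom <- stats::setNames(
      replicate(nrow(genome), NULL, simplify = FALSE), genome$chrom
    )
    w <- genome$length / sum(genome$length)
    draw_size <- function() {
      if (size_dist == "uniform") {
        return(floor(runif(1, size_range[1], size_range[2] + 1)))
      }
      repeat {
        s <- floor(stats::rlnorm(1, meanlog = log(15110), sdlog = 1.3))
        if (s >= size_range[1] && s <= size_range[2]) return(s)
      }
    }
    for (i in seq_len(n_cnvs)) {
      copies <- sample(copy_choices, 1L)
      ok <- FALSE
      cn <- NA_character_
      for (try in seq_len(max_tries)) {
        cn <- sample(genome$chrom, 1L, prob = w)
        len <- genome$length[genome$chrom == cn]
        size <- draw_size()
        if (size > len) next
        start <- floor(runif(1, 1, len - size + 2))
        end <- start + size - 1
        prev <- by_chrom[[cn]]
        if (is.null(prev) ||
            !any(start <= prev$end + min_gap & end >= prev$start - min_gap)) {
          by_chrom[[cn]] <- dplyr::bind_rows(prev, tibble(start = start, end = end))
          out[[i]] <- tibble(chrom = cn, start = start, end = end,
                             copies = as.integer(copies))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place CNV ", i, " without overlap after ", max_tries,
             " tries (last attempted chromosome: ", cn, ")", call. = FALSE)
      }
    }
    dplyr::bind_rows(out)
  })
  placed |> arrange(.data$chrom, .data$start)
}

#' Simulation settings for a two-channel hybridization
#'
#' @param baseline_intensity Expected linear intensity of a diploid probe in
#'   both channels (arbitrary fluorescence units, > 0).
#' @param noise_sd Standard deviation of independent Gaussian noise added to
#'   each channel's log2 intensity.
#' @param dye_bias_a,dye_bias_b Monotone power-law distortion applied to the
#'   test channel on the linear scale: `test' = a * test^b`. The defaults
#'   (1.2, 0.95) create the intensity-dependent dye bias that q-spline
#'   normalization exists to remove; `a = 1, b = 1` disables it.
#' @param gradient_amplitude Peak-to-peak amplitude, in log2 units across the
#'   array diagonal, of the smooth spatial artifact added to both channels
#'   (>= 0).
#' @param zero_copy_floor Effective copy number used for homozygous deletions
#'   (copies = 0), representing residual background hybridization; keeps
#'   intensities positive. Default 0.25 gives an expected log2 ratio of -3.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `cgh_sim_config`.
#' @export
sim_config <- function(baseline_intensity = 1000, noise_sd = 0.15,
                       dye_bias_a = 1.2, dye_bias_b = 0.95,
                       gradient_amplitude = 0.3, zero_copy_floor = 0.25,
                       seed = 1L) {
  if (baseline_intensity <= 0) abort_bad_arg("baseline_intensity must be positive")
  if (noise_sd < 0) abort_bad_arg("noise_sd must be >= 0")
  if (gradient_amplitude < 0) abort_bad_arg("gradient_amplitude must be >= 0")
  if (zero_copy_floor <= 0) abort_bad_arg("zero_copy_floor must be positive")
  structure(
    list(baseline_intensity = baseline_intensity, noise_sd = noise_sd,
         dye_bias_a = dye_bias_a, dye_bias_b = dye_bias_b,
         gradient_amplitude = gradient_amplitude,
         zero_copy_floor = zero_copy_floor, seed = as.integer(seed)),
    class = "cgh_sim_config"
  )
}

# Smooth spatial artifact on the log2 scale: a plane spanning
# `amplitude` log2 units across the array diagonal plus one low-frequency
# sinusoid at a quarter of the amplitude. u, v in [0, 1].
spatial_gradient <- function(u, v, amplitude) {
  amplitude * ((u + v) / 2 - 0.5 + 0.25 * sin(2 * pi * u) * cos(2 * pi * v))
}

#' Simulate a two-channel hybridization over a probe design
#'
#' Generates per-probe test (Cy3) and reference (Cy5) intensities. On the log2
#' scale, each channel starts at `log2(baseline_intensity)`, both receive the
#' same smooth spatial gradient over the scaled `(row, col)` grid and
#' independent Gaussian noise of sd `noise_sd`; the test channel additionally
#' carries the copy-number signal `log2(copies / 2)` at probes whose midpoint
#' `floor((start + end) / 2)` falls inside a planted CNV (copies of 0 are
#' floored at `zero_copy_floor`). Finally the test channel is distorted on the
#' linear scale by the monotone dye bias `a * x^b`.
#'
#' Noise draw order (for a fixed seed): first the test-channel vector, then
#' the reference-channel vector, each of length `nrow(design)`.
#'
#' @param design A probe design from [design_probes()].
#' @param truth A tibble of planted CNVs from [plant_cnvs()]; may have zero
#'   rows.
#' @param config A [sim_config()].
#' @return A tibble aligned to `design`: `probe_id`, `test_intensity`,
#'   `ref_intensity`, `row`, `col`.
#' @export
simulate_array <- function(design, truth = NULL, config = sim_config()) {
  stopifnot(inherits(config, "cgh_sim_config"))
  if (is.null(truth)) {
    truth <- tibble(chrom = character(), start = numeric(), end = numeric(),
                    copies = integer())
  }
  if (nrow(truth) > 0 && !all(truth$chrom %in% design$chrom)) {
    abort_bad_arg("truth intervals reference chromosomes absent from the design")
  }

  n <- nrow(design)
  mid <- floor((design$start + design$end) / 2)
  copies <- rep(2, n)
  if (nrow(truth) > 0) {
    for (cn in unique(truth$chrom)) {
      tr <- truth[truth$chrom == cn, ] |> arrange(.data$start)
      sel <- design$chrom == cn
      idx <- findInterval(mid[sel], tr$start)
      inside <- idx > 0 & mid[sel] <= tr$end[pmax(idx, 1L)]
      cp <- copies[sel]
      cp[inside] <- tr$copies[idx[inside]]
      copies[sel] <- cp
    }
  }
  ratio <- log2(pmax(copies, config$zero_copy_floor) / 2)

  u <- if (max(design$row) > 0) design$row / max(design$row) else rep(0, n)
  v <- if (max(design$col) > 0) design$col / max(design$col) else rep(0, n)
  g <- spatial_gradient(u, v, config$gradient_amplitude)

  noise <- withr::with_seed(config$seed, {
    list(test = rnorm(n, 0, config$noise_sd), ref = rnorm(n, 0, config$noise_sd))
  })

  lt <- log2(config$baseline_intensity) + ratio + g + noise$test
  lr <- log2(config$baseline_intensity) + g + noise$ref
  test <- config$dye_bias_a * (2^lt)^config$dye_bias_b

  tibble(
    probe_id = design$probe_id,
    test_intensity = test,
    ref_intensity = 2^lr,
    row = design$row,
    col = design$col
  )
}

#' Simulate a self-self hybridization
#'
#' The same DNA in both channels: no planted CNVs and no dye-bias asymmetry,
#' so the expected log2 ratio is 0 genome-wide and every downstream CNV call
#' is by construction a false positive. Spatial gradient and per-channel noise
#' are retained from `config`.
#'
#' @inheritParams simulate_array
#' @return A tibble as in [simulate_array()].
#' @export
simulate_self_self <- function(design, config = sim_config()) {
  cfg <- config
  cfg$dye_bias_a <- 1
  cfg$dye_bias_b <- 1
  simulate_array(design, truth = NULL, config = cfg)
}
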