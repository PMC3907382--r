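test_that("zero-jitter probe design tiles exactly at the requested spacing", {
  g <- genome_spec("chr1", 1650000)
  d <- design_probes(g, mean_spacing = 1650, probe_length = 60,
                     jitter_fraction = 0, seed = 1)
  expect_equal(nrow(d), 1000)
  expect_equal(unique(diff(d$start)), 1650)
  expect_true(all(d$end - d$start + 1 == 60))
  # row-major near-square grid, unique positions
  expect_equal(anyDuplicated(d[, c("row", "col")]), 0L)
  expect_true(max(d$row) <= ceiling(sqrt(nrow(d))))
})

test_that("empirical mean spacing converges to the target within 2%", {
  g <- genome_spec("chr1", 16.5e6) # ~1e4 probes
  d <- design_probes(g, mean_spacing = 1650, jitter_fraction = 0.3, seed = 7)
  expect_gt(nrow(d), 9000)
  expect_lt(abs(mean(diff(d$start)) - 1650) / 1650, 0.02)
})

test_that("jittered probe count matches an independent re-walk of the RNG stream", {
  g <- genome_spec("chr1", 1e5)
  d <- design_probes(g, mean_spacing = 1650, probe_length = 60,
                     jitter_fraction = 0.3, seed = 42)
  lo <- 1650 * 0.7
  hi <- 1650 * 1.3
  walk <- withr::with_seed(42, {
    pos <- 1
    starts <- numeric(0)
    while (pos + 59 <= 1e5) {
      starts <- c(starts, pos)
      pos <- pos + round(stats::runif(1, lo, hi))
    }
    starts
  })
  expect_equal(d$start, walk)
})

test_that("short chromosomes get zero probes with a warning", {
  g <- genome_spec(c("chr1", "tiny"), c(1e5, 800))
  expect_warning(d <- design_probes(g, seed = 1), "tiny")
  expect_equal(sum(d$chrom == "tiny"), 0)
})

test_that("plant_cnvs honours count, size range, copy choices and disjointness", {
  g <- tiny_genome(2, 5)
  expect_equal(nrow(plant_cnvs(g, 0)), 0)

  tr <- plant_cnvs(g, 50, size_range = c(6100, 570000), seed = 11)
  sizes <- tr$end - tr$start + 1
  expect_true(all(sizes >= 6100 & sizes <= 570000))
  expect_true(all(tr$copies %in% c(0L, 1L, 3L, 4L)))
  expect_true(all(tr$copies != 2L))

  tr10 <- plant_cnvs(g, 10, seed = 3)
  # exhaustive O(n^2) disjointness oracle
  for (i in seq_len(nrow(tr10))) {
    for (j in seq_len(nrow(tr10))) {
      if (i == j || tr10$chrom[i] != tr10$chrom[j]) next
      expect_true(tr10$start[i] > tr10$end[j] || tr10$end[i] < tr10$start[j])
    }
  }
})

test_that("uniform size option draws within the range", {
  g <- tiny_genome(2, 5)
  tr <- plant_cnvs(g, 20, size_range = c(10000, 50000), size_dist = "uniform",
                   seed = 5)
  sizes <- tr$end - tr$start + 1
  expect_true(all(sizes >= 10000 & sizes <= 50000))
})

test_that("noise-free simulation reproduces the planted signal exactly", {
  g <- genome_spec("chr1", 1e6)
  d <- design_probes(g, jitter_fraction = 0, seed = 1)
  cfg <- clean_config()

  flat <- simulate_array(d, NULL, cfg)
  expect_equal(log2(flat$test_intensity / flat$ref_intensity),
               rep(0, nrow(d)))

  truth <- tibble::tibble(chrom = "chr1", start = 4e5, end = 6e5, copies = 4L)
  ii <- simulate_array(d, truth, cfg)
  r <- log2(ii$test_intensity / ii$ref_intensity)
  mid <- floor((d$start + d$end) / 2)
  inside <- mid >= 4e5 & mid <= 6e5
  expect_equal(unique(r[inside]), 1)
  expect_equal(unique(r[!inside]), 0)
})

test_that("probe midpoint decides CNV membership", {
  g <- genome_spec("chr1", 1e5)
  d <- design_probes(g, jitter_fraction = 0, seed = 1)
  # CNV boundary placed so that one probe straddles it with midpoint outside
  p <- d[10, ]
  midp <- floor((p$start + p$end) / 2)
  truth <- tibble::tibble(chrom = "chr1", start = midp + 1, end = midp + 20000,
                          copies = 4L)
  ii <- simulate_array(d, truth, clean_config())
  r <- log2(ii$test_intensity / ii$ref_intensity)
  expect_equal(r[10], 0) # midpoint just outside -> diploid
  expect_equal(r[11], 1) # next probe inside
})

test_that("noisy simulation matches an independent re-derivation of the formula", {
  g <- genome_spec("chr1", 2e5)
  d <- design_probes(g, jitter_fraction = 0, seed = 2)
  truth <- tibble::tibble(chrom = "chr1", start = 5e4, end = 9e4, copies = 3L)
  cfg <- sim_config(noise_sd = 0.15, seed = 99)
  ii <- simulate_array(d, truth, cfg)

  # scripted re-application of the documented formula, same RNG order
  n <- nrow(d)
  mid <- floor((d$start + d$end) / 2)
  copies <- ifelse(mid >= 5e4 & mid <= 9e4, 3, 2)
  ratio <- log2(pmax(copies, cfg$zero_copy_floor) / 2)
  u <- d$row / max(d$row)
  v <- d$col / max(d$col)
  grad <- cfg$gradient_amplitude *
    ((u + v) / 2 - 0.5 + 0.25 * sin(2 * pi * u) * cos(2 * pi * v))
  noise <- withr::with_seed(99, list(test = rnorm(n, 0, 0.15),
                                     ref = rnorm(n, 0, 0.15)))
  lt <- log2(cfg$baseline_intensity) + ratio + grad + noise$test
  lr <- log2(cfg$baseline_intensity) + grad + noise$ref
  expect_equal(ii$test_intensity, cfg$dye_bias_a * (2^lt)^cfg$dye_bias_b)
  expect_equal(ii$ref_intensity, 2^lr)
})

test_that("zero-copy CNVs keep intensities positive via the background floor", {
  g <- genome_spec("chr1", 1e5)
  d <- design_probes(g, jitter_fraction = 0, seed = 1)
  truth <- tibble::tibble(chrom = "chr1", start = 1, end = 5e4, copies = 0L)
  ii <- simulate_array(d, truth, clean_config())
  expect_true(all(ii$test_intensity > 0))
  r <- log2(ii$test_intensity / ii$ref_intensity)
  expect_equal(min(r), -3) # log2(0.25 / 2)
})

test_that("self-self arrays are ratio-1 without noise and deterministic with it", {
  g <- genome_spec("chr1", 2e5)
  d <- design_probes(g, seed = 1)
  cfg0 <- sim_config(noise_sd = 0, gradient_amplitude = 0.3, seed = 1)
  ss <- simulate_self_self(d, cfg0)
  expect_equal(ss$test_intensity / ss$ref_intensity, rep(1, nrow(d)))

  cfg <- sim_config(noise_sd = 0.15, seed = 5)
  a <- simulate_self_self(d, cfg)
  b <- simulate_self_self(d, cfg)
  expect_identical(a, b)
})

test_that("simulation is deterministic in the config seed and validates input", {
  g <- genome_spec("chr1", 2e5)
  d <- design_probes(g, seed = 1)
  cfg <- sim_config(seed = 3)
  expect_identical(simulate_array(d, NULL, cfg), simulate_array(d, NULL, cfg))
  expect_error(sim_config(baseline_intensity = -1), "positive")
  bad_truth <- tibble::tibble(chrom = "chrZ", start = 1, end = 10, copies = 3L)
  expect_error(simulate_array(d, bad_truth, cfg), "absent")
})
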