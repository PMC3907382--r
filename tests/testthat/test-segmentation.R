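test_that("constant and two-level sequences are segmented exactly", {
  fit <- dp_segment(rep(2.5, 20), k_max = 5)
  expect_equal(fit$chosen_k, 1)
  expect_equal(fit$sse_by_k[1], 0)

  fit2 <- dp_segment(c(0, 0, 0, 1, 1, 1), k_max = 3, k = 2)
  expect_equal(fit2$segments$last[1], 3)
  expect_equal(fit2$sse_by_k[2], 0)
  expect_equal(fit2$segments$mean, c(0, 1))
})

test_that("dp_segment agrees with exhaustive enumeration on 15 points, k = 3", {
  x <- withr::with_seed(15, rnorm(15))
  bf <- brute_force_segment(x, 3)
  dp <- dp_segment(x, k_max = 3, k = 3)
  expect_equal(dp$sse_by_k[3], bf$cost)
  expect_equal(head(dp$segments$last, -1), bf$breakpoints)
})

test_that("brute-force oracle behaves on degenerate and random inputs", {
  expect_equal(brute_force_segment(5, 1)$cost, 0)

  bf <- brute_force_segment(c(0, 10), 2)
  expect_equal(bf$cost, 0)
  expect_equal(bf$breakpoints, 1L)

  # optimality: never beaten by random valid partitions
  x <- withr::with_seed(8, rnorm(18))
  k <- 3
  bf <- brute_force_segment(x, k)
  block_sse <- function(a, b) sum((x[a:b] - mean(x[a:b]))^2)
  withr::with_seed(9, {
    for (i in 1:10) {
      bp <- sort(sample(17, k - 1))
      bounds <- c(0, bp, 18)
      cost <- sum(vapply(seq_len(k), function(s) {
        block_sse(bounds[s] + 1, bounds[s + 1])
      }, numeric(1)))
      expect_gte(cost, bf$cost - 1e-12)
    }
  })
  expect_error(brute_force_segment(rnorm(30), 2), "n <= 25")
})

test_that("sse_by_k is non-increasing and costs conserve the track mean", {
  x <- withr::with_seed(21, rnorm(200))
  fit <- dp_segment(x, k_max = 12)
  expect_true(all(diff(fit$sse_by_k) <= 1e-9))
  w_mean <- sum(fit$segments$mean * fit$segments$n_probes) / length(x)
  expect_equal(w_mean, mean(x), tolerance = 1e-9)
})

test_that("input validation rejects bad k_max and non-finite values", {
  expect_error(dp_segment(rnorm(5), k_max = 6), "k_max")
  expect_error(dp_segment(c(1, NA, 2), k_max = 2), "finite")
  expect_error(dp_segment(numeric(0), k_max = 1), "non-empty")
})

test_that("a level shift is detected far better than its permutation", {
  x <- withr::with_seed(4, c(rnorm(50), rnorm(50, 1)))
  gain_signal <- dp_segment(x, 2, k = 1)$sse_by_k[1] -
    dp_segment(x, 2, k = 2)$sse_by_k[2]
  withr::with_seed(5, {
    for (i in 1:5) {
      xs <- sample(x)
      gain_perm <- dp_segment(xs, 2, k = 1)$sse_by_k[1] -
        dp_segment(xs, 2, k = 2)$sse_by_k[2]
      expect_lt(gain_perm, gain_signal)
    }
  })
})

test_that("segment_track recovers a planted CNV exactly without noise", {
  g <- genome_spec("chr1", 5e5)
  d <- design_probes(g, jitter_fraction = 0, seed = 1)
  mid <- floor((d$start + d$end) / 2)
  truth <- tibble::tibble(chrom = "chr1", start = mid[100], end = mid[109],
                          copies = 4L)
  ii <- simulate_array(d, truth, clean_config())
  tr <- to_log2_track(ii, d)

  flat <- segment_track(to_log2_track(simulate_array(d, NULL, clean_config()), d), d)
  expect_equal(nrow(flat$segments), 1)

  seg <- segment_track(tr, d)
  expect_equal(nrow(seg$segments), 3)
  expect_equal(seg$segments$mean_log2, c(0, 1, 0))
  expect_equal(seg$segments$n_probes[2], 10)
})

test_that("segment means of a noisy planted CNV concentrate around the truth", {
  g <- genome_spec("chr1", 2e6)
  d <- design_probes(g, jitter_fraction = 0, seed = 2)
  mid <- floor((d$start + d$end) / 2)
  truth <- tibble::tibble(chrom = "chr1", start = mid[500], end = mid[549],
                          copies = 4L)
  cfg <- sim_config(noise_sd = 0.15, dye_bias_a = 1, dye_bias_b = 1,
                    gradient_amplitude = 0, seed = 3)
  ii <- simulate_array(d, truth, cfg)
  seg <- segment_track(to_log2_track(ii, d), d)
  cnv_seg <- seg$segments |> dplyr::filter(mean_log2 > 0.5)
  expect_equal(nrow(cnv_seg), 1)
  # per-probe ratio noise is sqrt(2) * 0.15; allow 3 standard errors
  expect_lt(abs(cnv_seg$mean_log2 - 1), 3 * sqrt(2) * 0.15 / sqrt(50))
})

test_that("segments partition every chromosome with no gaps or overlaps", {
  g <- genome_spec(c("chr1", "chr2"), c(1e6, 5e5))
  d <- design_probes(g, seed = 4)
  ii <- simulate_array(d, NULL, sim_config(seed = 4))
  seg <- segment_track(preprocess_array(ii, d), d)
  for (cn in unique(seg$segments$chrom)) {
    ss <- seg$segments |> dplyr::filter(chrom == cn)
    n_chr <- sum(d$chrom == cn)
    expect_equal(ss$first[1], 1)
    expect_equal(ss$last[nrow(ss)], n_chr)
    if (nrow(ss) > 1) expect_equal(ss$first[-1], head(ss$last, -1) + 1)
    expect_equal(sum(ss$n_probes), n_chr)
  }
})

test_that("tidy and glance expose segments and fit summaries", {
  x <- withr::with_seed(6, c(rnorm(30), rnorm(30, 2)))
  fit <- dp_segment(x, k_max = 4)
  td <- generics::tidy(fit)
  gl <- generics::glance(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$n_probes), 60)
  expect_equal(gl$chosen_k, fit$chosen_k)

  g <- genome_spec("chr1", 2e5)
  d <- design_probes(g, seed = 7)
  seg <- segment_track(to_log2_track(simulate_array(d, NULL, clean_config()), d), d)
  expect_equal(nrow(generics::glance(seg)), 1)
  expect_named(generics::tidy(seg),
               c("chrom", "start", "end", "first", "last", "n_probes",
                 "mean_log2"))
})
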