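call_row <- function(sample, chrom, start, end, status = "gain") {
  tibble::tibble(sample_id = sample, chrom = chrom, start = start, end = end,
                 status = status, mean_log2 = ifelse(status == "gain", 1, -1),
                 n_probes = 10L)
}

test_that("overlapping calls of mixed status merge into one 'both' CNVR", {
  calls <- dplyr::bind_rows(
    call_row("A", "chr1", 100, 200, "gain"),
    call_row("B", "chr1", 150, 300, "loss")
  )
  cnvrs <- merge_to_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$start, 100)
  expect_equal(cnvrs$end, 300)
  expect_equal(cnvrs$status, "both")
  expect_equal(cnvrs$samples[[1]], c("A", "B"))
})

test_that("book-ended calls (0 shared bp) do not merge", {
  calls <- dplyr::bind_rows(
    call_row("A", "chr1", 100, 200),
    call_row("B", "chr1", 201, 300)
  )
  expect_equal(nrow(merge_to_cnvrs(calls)), 2)
  # 1 bp of sharing does merge
  calls2 <- dplyr::bind_rows(
    call_row("A", "chr1", 100, 200),
    call_row("B", "chr1", 200, 300)
  )
  expect_equal(nrow(merge_to_cnvrs(calls2)), 1)
})

test_that("total CNVR length equals the bp-marking union on random call sets", {
  calls <- random_calls(100, seed = 42)
  cnvrs <- merge_to_cnvrs(calls)
  expect_equal(sum(cnvrs$end - cnvrs$start + 1), bp_marking_union(calls, 1e5))
  expect_lte(nrow(cnvrs), nrow(calls))

  # merging is idempotent: re-merging the regions is a fixed point
  again <- merge_to_cnvrs(cnvrs |>
                            dplyr::mutate(sample_id = "merged",
                                          mean_log2 = 0, n_probes = 1L))
  expect_equal(again[, c("chrom", "start", "end")],
               cnvrs[, c("chrom", "start", "end")])
})

test_that("cnvr_status reduces member statuses correctly", {
  expect_equal(cnvr_status(c("gain", "gain")), "gain")
  expect_equal(cnvr_status("loss"), "loss")
  expect_equal(cnvr_status(c("gain", "loss")), "both")
  expect_error(cnvr_status(character(0)), "at least one")
})

test_that("sharing labels follow the overlap-component rule", {
  single <- call_row("A", "chr1", 100, 200)
  expect_equal(label_sharing(single)$sharing, "breed_specific")

  dup <- dplyr::bind_rows(call_row("A", "chr1", 100, 200),
                          call_row("B", "chr1", 100, 200))
  lab <- label_sharing(dup)
  expect_equal(lab$sharing, c("shared", "shared"))
  expect_equal(lab$n_samples_component, c(2L, 2L))

  # chain: A overlaps B, B overlaps C, A and C disjoint -> all shared(3)
  chain <- dplyr::bind_rows(
    call_row("A", "chr1", 100, 200),
    call_row("B", "chr1", 180, 400),
    call_row("C", "chr1", 350, 500)
  )
  lab <- label_sharing(chain)
  expect_equal(lab$sharing, rep("shared", 3))
  expect_equal(lab$n_samples_component, rep(3L, 3))

  # partition property: breed_specific + shared = total
  calls <- random_calls(60, seed = 7)
  lab <- label_sharing(calls)
  expect_equal(nrow(lab), nrow(calls))
  expect_true(all(lab$sharing %in% c("breed_specific", "shared")))
})

test_that("common_in_all matches a brute-force filter", {
  calls <- random_calls(80, seed = 13, n_samples = 4)
  cnvrs <- merge_to_cnvrs(calls)
  all_s <- paste0("s", 1:4)
  got <- common_in_all(cnvrs, all_s)
  brute <- cnvrs[vapply(cnvrs$samples,
                        function(s) all(all_s %in% s), logical(1)), ]
  expect_equal(got$cnvr_id, brute$cnvr_id)
  expect_equal(nrow(common_in_all(cnvrs, c(all_s, "s99"))), 0)
})

test_that("compare_sets counts overlaps like a quadratic scan", {
  a <- merge_to_cnvrs(random_calls(40, seed = 1))
  b <- merge_to_cnvrs(random_calls(40, seed = 2))
  got <- compare_sets(a, b)
  brute <- sum(vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start <= a$end[i] & b$end >= a$start[i])
  }, logical(1)))
  expect_equal(got$n_a_overlapping_b, brute)

  expect_equal(compare_sets(a, a)$n_a_overlapping_b, nrow(a))
  b_far <- b |> dplyr::mutate(chrom = paste0(chrom, "_other"))
  expect_equal(compare_sets(a, b_far)$n_a_overlapping_b, 0)
})

test_that("gene overlap honours the >= 1 bp rule and deduplicates globally", {
  cnvrs <- tibble::tibble(cnvr_id = c("r1", "r2"), chrom = "chr1",
                          start = c(1000, 5000), end = c(2000, 6000),
                          status = "gain")
  ann <- tibble::tibble(
    gene_id = c("inside", "past_end", "spans_both_edge"),
    chrom = "chr1",
    start = c(1200, 2001, 1900),
    end = c(1300, 2100, 2200),
    biotype = "protein_coding"
  )
  hits <- genes_overlapping(cnvrs, ann)
  expect_setequal(hits$gene_id, c("inside", "spans_both_edge"))
  expect_equal(attr(hits, "n_genes"), 2L)

  ann_bad <- ann |> dplyr::mutate(chrom = c("chr1", "chrZ", "chr1"))
  expect_warning(genes_overlapping(cnvrs, ann_bad), "chrZ")

  # random sets against an all-pairs scan
  cn <- merge_to_cnvrs(random_calls(30, seed = 5))
  genes <- withr::with_seed(6, tibble::tibble(
    gene_id = paste0("g", 1:50), chrom = sample(c("chr1", "chr2"), 50, TRUE),
    start = sample.int(95000, 50), biotype = NA_character_
  ) |> dplyr::mutate(end = start + 2000))
  hits <- genes_overlapping(cn, genes)
  brute <- sum(vapply(seq_len(nrow(genes)), function(i) {
    any(cn$chrom == genes$chrom[i] & cn$start <= genes$end[i] &
          cn$end >= genes$start[i])
  }, logical(1)))
  expect_equal(attr(hits, "n_genes"), brute)
})

test_that("chromosome summary reproduces printed-table arithmetic", {
  # chr12-like row: 6 CNVRs totaling 2,611,353 bp on a 33,091,231 bp chromosome
  tbl <- tibble::tibble(chrom = "12", n_cnvrs = 6L, n_genes = 0L,
                        cnvr_bp = 2611353, chrom_bp = 33091231)
  syn <- synthetic_cnvrs_from_table(tbl)
  row <- chromosome_summary(syn$cnvrs, syn$genome)[1, ]
  expect_equal(row$pct_of_chrom, 7.89)
  expect_equal(row$mean_cnvr_kb, 435.23)

  # empty chromosome -> zero row
  g2 <- genome_spec(c("12", "empty"), c(33091231, 5e6))
  cs <- chromosome_summary(syn$cnvrs, g2)
  empty_row <- cs[cs$chrom == "empty", ]
  expect_equal(empty_row$n_cnvrs, 0L)
  expect_equal(empty_row$pct_of_chrom, 0)
  expect_equal(empty_row$mean_cnvr_kb, 0)

  # random CNVRs: totals equal an independent summation of raw intervals
  calls <- random_calls(50, seed = 3)
  cn <- merge_to_cnvrs(calls)
  g3 <- genome_spec(c("chr1", "chr2"), c(1e5, 1e5))
  cs3 <- chromosome_summary(cn, g3)
  tot <- cs3[cs3$chrom == "Total", ]
  expect_equal(tot$cnvr_bp, sum(cn$end - cn$start + 1))
  expect_equal(tot$n_cnvrs, nrow(cn))
})

test_that("the totals row percentage uses the autosomal denominator", {
  g <- genome_spec(c("1", "X"), c(1e6, 1e6))
  cnvrs <- tibble::tibble(cnvr_id = "r1", chrom = "1", start = 1, end = 1e5,
                          status = "loss")
  tot <- chromosome_summary(cnvrs, g) |> dplyr::filter(chrom == "Total")
  expect_equal(tot$pct_of_chrom, 10) # 1e5 of the 1e6 autosomal bp, X excluded
  expect_equal(tot$chrom_bp, 2e6)
})

test_that("size bins are half-open and partition the CNVR set", {
  cnvrs <- tibble::tibble(
    cnvr_id = paste0("r", 1:4), chrom = "chr1",
    start = c(1, 1e5, 2e6, 9e6),
    end = c(9999, 1e5 + 49999, 2e6 + 99999, 9.6e6),
    status = "gain"
  )
  b <- size_bins(cnvrs)
  expect_equal(b$n, c(1L, 0L, 1L, 1L, 1L))

  boundary <- tibble::tibble(cnvr_id = "r", chrom = "chr1", start = 1,
                             end = 50000, status = "gain")
  b2 <- size_bins(boundary)
  expect_equal(b2$n[b2$bin == "50-100 Kb"], 1L)

  cn <- merge_to_cnvrs(random_calls(70, seed = 9))
  expect_equal(sum(size_bins(cn)$n), nrow(cn))
})

test_that("status summary reproduces printed means and shares", {
  tabs <- horse_summary_tables()
  ss <- status_summary(synthetic_cnvrs_from_status(tabs$status))
  expect_equal(ss$mean_kb[ss$status == "gain"], 45.92)
  expect_equal(ss$mean_kb[ss$status == "loss"], 33.87)
  expect_equal(ss$pct_of_count[ss$status == "loss"], 66.29)

  one <- tibble::tibble(cnvr_id = "r", chrom = "c", start = 1, end = 1000,
                        status = "gain")
  s1 <- status_summary(one)
  expect_equal(s1$pct_of_total_length[s1$status == "gain"], 100)

  cn <- merge_to_cnvrs(random_calls(40, seed = 10))
  sr <- status_summary(cn)
  expect_equal(sum(sr$total_bp), sum(cn$end - cn$start + 1))
  expect_equal(sum(sr$n_cnvrs), nrow(cn))
  expect_lt(abs(sum(sr$pct_of_total_length) - 100), 0.02)
})

test_that("sample summary counts per individual and in total", {
  calls <- dplyr::bind_rows(
    call_row("A", "chr1", 1, 10000, "gain"),
    call_row("A", "chr1", 30000, 35000, "loss"),
    call_row("B", "chr2", 1, 20000, "loss")
  )
  ss <- sample_summary(calls)
  expect_equal(ss$n_cnvs[ss$sample_id == "A"], 2L)
  expect_equal(ss$n_cnvs[ss$sample_id == "Total"], 3L)
  expect_equal(ss$n_losses[ss$sample_id == "Total"], 2L)
})
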