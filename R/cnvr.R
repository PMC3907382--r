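# Shared helper: assign calls on one chromosome-sorted tibble to transitive
# overlap components (>= 1 shared bp; book-ended intervals do not merge).
overlap_components <- function(calls) {
  calls |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(
      .reach = cummax(dplyr::lag(.data$end, default = -Inf)),
      .component = cumsum(.data$start > .data$.reach)
    ) |>
    ungroup() |>
    select(-".reach")
}

#' Merge per-sample CNV calls into CNV regions (CNVRs)
#'
#' A CNVR is the transitive closure of the "overlaps by at least 1 bp"
#' relation among calls on the same chromosome, across all samples. Each CNVR
#' spans `min(start)` to `max(end)` of its member calls; its status is gain if
#' all members are gains, loss if all are losses, and both otherwise. Merging
#' is idempotent: re-merging the resulting regions is a fixed point.
#'
#' @param calls A tibble of CNV calls from [call_cnvs()], typically
#'   concatenated across samples.
#' @return A tibble of CNVRs: `cnvr_id`, `chrom`, `start`, `end`, `status`,
#'   `n_calls`, `n_samples`, plus list columns `samples` (sorted unique sample
#'   ids) and `members` (the member call rows).
#' @export
merge_to_cnvrs <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(cnvr_id = character(), chrom = character(), start = numeric(),
                  end = numeric(), status = character(), n_calls = integer(),
                  n_samples = integer(), samples = list(), members = list()))
  }
  if (any(calls$end < calls$start)) abort_bad_arg("calls contain end < start")
  comp <- overlap_components(calls)
  out <- comp |>
    group_by(.data$chrom, .data$.component) |>
    summarise(
      # members must be captured before the summary columns shadow the
      # originals in the data mask
      members = list({
        m <- pick(dplyr::everything())
        m$chrom <- dplyr::cur_group()$chrom
        m[, union("chrom", names(m))]
      }),
      start = min(.data$start),
      end = max(.data$end),
      status = cnvr_status(.data$status),
      n_calls = dplyr::n(),
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = list(sort(unique(.data$sample_id))),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    select(-".component") |>
    select("chrom", "start", "end", "status", "n_calls", "n_samples",
           "samples", "members")
  out |>
    mutate(cnvr_id = sprintf("CNVR%04d", dplyr::row_number()), .before = 1)
}

#' Status of a CNVR from its member calls
#'
#' @param status Character vector of member statuses (`"gain"` / `"loss"`),
#'   non-empty.
#' @return `"gain"` if all members are gains, `"loss"` if all losses,
#'   `"both"` if mixed.
#' @export
cnvr_status <- function(status) {
  if (length(status) == 0) abort_bad_arg("a CNVR needs at least one member call")
  has_gain <- any(status == "gain")
  has_loss <- any(status == "loss")
  if (has_gain && has_loss) "both" else if (has_gain) "gain" else "loss"
}

#' Label calls as breed-specific or shared
#'
#' Calls are grouped into transitive overlap components (>= 1 bp, per
#' chromosome, across samples). A call in a component containing calls from
#' two or more distinct samples is `shared`; a call whose component involves
#' only its own sample is `breed_specific`. The component's distinct-sample
#' count is reported alongside, so an A-B-C overlap chain marks all three
#' calls as shared among 3 samples even if A and C do not touch.
#'
#' @param calls A tibble of CNV calls across samples.
#' @return The calls with two extra columns: `sharing`
#'   (`"breed_specific"` / `"shared"`) and `n_samples_component`.
#' @export
label_sharing <- function(calls) {
  if (nrow(calls) == 0) {
    return(calls |> mutate(sharing = character(0),
                           n_samples_component = integer(0)))
  }
  overlap_components(calls) |>
    group_by(.data$chrom, .data$.component) |>
    mutate(
      n_samples_component = dplyr::n_distinct(.data$sample_id),
      sharing = ifelse(.data$n_samples_component >= 2L, "shared",
                       "breed_specific")
    ) |>
    ungroup() |>
    select(-".component")
}

#' CNVRs present in every sample
#'
#' @param cnvrs A CNVR tibble from [merge_to_cnvrs()].
#' @param all_samples Character vector of every sample in the study.
#' @return The subset of CNVRs whose member-sample set contains all of
#'   `all_samples`.
#' @export
common_in_all <- function(cnvrs, all_samples) {
  if (length(all_samples) == 0) abort_bad_arg("all_samples must be non-empty")
  keep <- purrr::map_lgl(cnvrs$samples, ~ all(all_samples %in% .x))
  cnvrs[keep, , drop = FALSE]
}

#' Count regions of one set overlapping another
#'
#' Counts how many intervals of `a` share at least 1 bp with any interval of
#' `b` — the standard way to compare a CNVR catalogue against a previously
#' published one.
#'
#' @param a,b Interval tibbles with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return A list: `n_a_overlapping_b` (integer) and `pairs`, a tibble of
#'   overlapping index pairs (`idx_a`, `idx_b`).
#' @export
compare_sets <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(n_a_overlapping_b = 0L,
                pairs = tibble(idx_a = integer(), idx_b = integer())))
  }
  gr_a <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  # disjoint chromosome sets are a legitimate comparison (zero overlaps), not
  # a condition to warn about
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L)
  )
  pairs <- tibble(idx_a = S4Vectors::queryHits(hits),
                  idx_b = S4Vectors::subjectHits(hits))
  list(n_a_overlapping_b = dplyr::n_distinct(pairs$idx_a), pairs = pairs)
}

#' Genes within or overlapping CNVRs
#'
#' A gene is reported for a CNVR when the two intervals share at least 1 bp.
#' Annotation records on chromosomes absent from the CNVR set are skipped with
#' a warning.
#'
#' @param cnvrs A CNVR tibble.
#' @param annotation A gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, optionally `biotype`), e.g. from [read_gene_annotation()].
#' @return A tibble with one row per (CNVR, gene) overlap: `cnvr_id`,
#'   `gene_id`, gene coordinates, and `biotype` when present. The number of
#'   distinct genes hit is attached as attribute `n_genes`.
#' @export
genes_overlapping <- function(cnvrs, annotation) {
  if (any(annotation$end < annotation$start)) {
    abort_bad_arg("annotation contains end < start")
  }
  unknown <- setdiff(unique(annotation$chrom), unique(cnvrs$chrom))
  if (length(unknown) > 0) {
    warning("annotation chromosomes absent from the CNVR set skipped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    annotation <- annotation |> filter(!.data$chrom %in% unknown)
  }
  empty <- tibble(cnvr_id = character(), gene_id = character(),
                  chrom = character(), start = numeric(), end = numeric())
  if (nrow(cnvrs) == 0 || nrow(annotation) == 0) {
    attr(empty, "n_genes") <- 0L
    return(empty)
  }
  gr_c <- GenomicRanges::GRanges(cnvrs$chrom,
                                 IRanges::IRanges(cnvrs$start, cnvrs$end))
  gr_g <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start, annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g, minoverlap = 1L)
  out <- dplyr::bind_cols(
    tibble(cnvr_id = cnvrs$cnvr_id[S4Vectors::queryHits(hits)]),
    annotation[S4Vectors::subjectHits(hits), , drop = FALSE]
  ) |> arrange(.data$cnvr_id, .data$start)
  attr(out, "n_genes") <- dplyr::n_distinct(out$gene_id)
  out
}

#' Per-chromosome CNVR summary table
#'
#' For each chromosome of the genome: number of CNVRs, number of distinct
#' genes they hit, total CNVR length (bp), chromosome length (bp), CNVR
#' coverage as a percentage of the chromosome, and mean CNVR size in Kb.
#' Percentages and means are rounded half-up to 2 decimals, matching how such
#' tables are conventionally printed. A `Total` row is appended; its coverage
#' percentage is computed over autosomes only (sex chromosomes are excluded
#' from the denominator because tiling CNV surveys in mares call autosomes
#' only, while the assembly length table still lists X).
#'
#' @param cnvrs A CNVR tibble (any tibble with `chrom`, `start`, `end`; a
#'   `cnvr_id` column is used for gene counting when `annotation` is given).
#' @param genome A [genome_spec()] covering all CNVR chromosomes.
#' @param annotation Optional gene annotation (see [genes_overlapping()]);
#'   when `NULL`, gene counts are 0.
#' @return A tibble with one row per chromosome plus a `Total` row: `chrom`,
#'   `n_cnvrs`, `n_genes`, `cnvr_bp`, `chrom_bp`, `pct_of_chrom`,
#'   `mean_cnvr_kb`.
#' @export
chromosome_summary <- function(cnvrs, genome, annotation = NULL) {
  if (!all(unique(cnvrs$chrom) %in% genome$chrom)) {
    abort_bad_arg("genome does not cover all CNVR chromosomes")
  }
  gene_hits <- if (!is.null(annotation) && nrow(cnvrs) > 0) {
    cn <- if ("cnvr_id" %in% names(cnvrs)) cnvrs else
      cnvrs |> mutate(cnvr_id = sprintf("CNVR%04d", dplyr::row_number()))
    genes_overlapping(cn, annotation) |>
      left_join(cn |> select("cnvr_id", cnvr_chrom = "chrom"), by = "cnvr_id")
  } else {
    tibble(gene_id = character(), cnvr_chrom = character())
  }

  per_chrom <- purrr::map(genome$chrom, function(cn) {
    cc <- cnvrs |> filter(.data$chrom == cn)
    len <- genome$length[genome$chrom == cn]
    total <- sum(cc$end - cc$start + 1)
    ng <- gene_hits |> filter(.data$cnvr_chrom == cn)
    tibble(
      chrom = cn,
      n_cnvrs = nrow(cc),
      n_genes = dplyr::n_distinct(ng$gene_id),
      cnvr_bp = total,
      chrom_bp = len,
      pct_of_chrom = round_half_up(100 * total / len, 2),
      mean_cnvr_kb = if (nrow(cc) > 0) round_half_up(total / nrow(cc) / 1000, 2) else 0
    )
  }) |> dplyr::bind_rows()

  autosome_bp <- sum(genome$length[!is_sex_chrom(genome$chrom)])
  total_bp <- sum(per_chrom$cnvr_bp)
  n_total <- sum(per_chrom$n_cnvrs)
  totals <- tibble(
    chrom = "Total",
    n_cnvrs = n_total,
    n_genes = dplyr::n_distinct(gene_hits$gene_id),
    cnvr_bp = total_bp,
    chrom_bp = sum(genome$length),
    pct_of_chrom = round_half_up(100 * total_bp / autosome_bp, 2),
    mean_cnvr_kb = if (n_total > 0) round_half_up(total_bp / n_total / 1000, 2) else 0
  )
  dplyr::bind_rows(per_chrom, totals)
}

#' CNVR size distribution over standard bins
#'
#' Bins CNVR sizes (`end - start + 1` bp) into the five conventional ranges
#' 1-10 Kb, 10-50 Kb, 50-100 Kb, 100-500 Kb and > 500 Kb. Bins are half-open
#' `[lo, hi)`: a region of exactly 50,000 bp falls in 50-100 Kb.
#'
#' @param cnvrs A CNVR tibble.
#' @return A tibble with columns `bin` (ordered factor) and `n`; every bin is
#'   present, summing to `nrow(cnvrs)`.
#' @export
size_bins <- function(cnvrs) {
  labels <- c("1-10 Kb", "10-50 Kb", "50-100 Kb", "100-500 Kb", ">500 Kb")
  size_kb <- (cnvrs$end - cnvrs$start + 1) / 1000
  bin <- cut(size_kb, breaks = c(0, 10, 50, 100, 500, Inf), right = FALSE,
             labels = labels)
  tibble(bin = factor(labels, levels = labels)) |>
    left_join(tibble(bin = bin) |> dplyr::count(.data$bin), by = "bin") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' CNVR characteristics by status
#'
#' One row per status (gain, loss, both): region count, the count's share of
#' all regions, total length in bp, mean size in Kb, and the status's share of
#' the total CNVR length in percent. Rounding is half-up to 2 decimals; each
#' percentage column sums to 100 within rounding error.
#'
#' @param cnvrs A CNVR tibble with a `status` column.
#' @return A tibble: `status`, `n_cnvrs`, `pct_of_count`, `total_bp`,
#'   `mean_kb`, `pct_of_total_length`.
#' @export
status_summary <- function(cnvrs) {
  grand <- sum(cnvrs$end - cnvrs$start + 1)
  purrr::map(c("gain", "loss", "both"), function(st) {
    cc <- cnvrs |> filter(.data$status == st)
    total <- sum(cc$end - cc$start + 1)
    tibble(
      status = st,
      n_cnvrs = nrow(cc),
      pct_of_count = if (nrow(cnvrs) > 0) {
        round_half_up(100 * nrow(cc) / nrow(cnvrs), 2)
      } else 0,
      total_bp = total,
      mean_kb = if (nrow(cc) > 0) round_half_up(total / nrow(cc) / 1000, 2) else 0,
      pct_of_total_length = if (grand > 0) round_half_up(100 * total / grand, 2) else 0
    )
  }) |> dplyr::bind_rows()
}

#' Per-sample CNV call summary
#'
#' Counts calls, gains and losses per sample with the mean call size in Kb,
#' plus a `Total` row — the per-individual summary conventionally reported for
#' multi-sample CNV surveys.
#'
#' @param calls A tibble of CNV calls across samples.
#' @return A tibble: `sample_id`, `n_cnvs`, `n_gains`, `n_losses`,
#'   `mean_size_kb`.
#' @export
sample_summary <- function(calls) {
  per <- calls |>
    group_by(.data$sample_id) |>
    summarise(
      n_cnvs = dplyr::n(),
      n_gains = sum(.data$status == "gain"),
      n_losses = sum(.data$status == "loss"),
      mean_size_kb = round_half_up(mean(.data$end - .data$start + 1) / 1000, 2),
      .groups = "drop"
    )
  totals <- tibble(
    sample_id = "Total",
    n_cnvs = nrow(calls),
    n_gains = sum(calls$status == "gain"),
    n_losses = sum(calls$status == "loss"),
    mean_size_kb = round_half_up(mean(calls$end - calls$start + 1) / 1000, 2)
  )
  dplyr::bind_rows(per, totals)
}
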