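#' Published horse CNVR summary tables
#'
#' Reference summary tables from a published aCGH survey of copy number
#' variation across six horse breeds, shipped with the package as plain TSV:
#'
#' * `chromosome`: per-chromosome CNVR count, gene count, total CNVR length
#'   (bp) and chromosome length (bp) for the 31 autosomes and X (which carried
#'   no calls — the survey analysed autosomes only).
#' * `status`: CNVR count and total length by status (gain / loss / both).
#' * `breed`: per-breed CNV, gain and loss counts.
#'
#' These tables are inputs for arithmetic-reproduction checks: feeding the
#' summary operations intervals with these per-chromosome totals must
#' reproduce the survey's printed coverage percentages and mean sizes.
#'
#' @return A list of three tibbles: `chromosome`, `status`, `breed`.
#' @export
horse_summary_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "cghcnv",
                                  mustWork = TRUE)
  list(
    chromosome = readr::read_tsv(
      path("horse_cnvr_chromosome_table.tsv"),
      col_types = readr::cols(chrom = "c", n_cnvrs = "i", n_genes = "i",
                              cnvr_bp = "d", chrom_bp = "d")),
    status = readr::read_tsv(
      path("horse_cnvr_status_table.tsv"),
      col_types = readr::cols(status = "c", n_cnvrs = "i", total_bp = "d")),
    breed = readr::read_tsv(
      path("horse_cnv_breed_table.tsv"),
      col_types = readr::cols(breed = "c", n_cnvs = "i", n_gains = "i",
                              n_losses = "i"))
  )
}

#' Build synthetic intervals matching a chromosome summary table
#'
#' Constructs, for each chromosome, `n_cnvrs` disjoint intervals whose lengths
#' sum exactly to the table's `cnvr_bp`, together with a matching genome and a
#' synthetic gene annotation placing exactly `n_genes` distinct 1-bp genes
#' inside the chromosome's first interval. Running [chromosome_summary()] on
#' the result must reproduce the table's derived columns (coverage percent,
#' mean size) exactly — a pure arithmetic check that is independent of where
#' the intervals sit.
#'
#' @param tbl The `chromosome` tibble from [horse_summary_tables()] (or any
#'   table with columns `chrom`, `n_cnvrs`, `n_genes`, `cnvr_bp`, `chrom_bp`).
#' @param gap Distance in bp between consecutive synthetic intervals.
#' @return A list: `cnvrs` (tibble with `cnvr_id`, `chrom`, `start`, `end`,
#'   `status`), `genome` (a [genome_spec()]), `annotation` (tibble with
#'   `gene_id`, `chrom`, `start`, `end`, `biotype`).
#' @export
synthetic_cnvrs_from_table <- function(tbl, gap = 10000) {
  cnvr_rows <- list()
  gene_rows <- list()
  for (i in seq_len(nrow(tbl))) {
    n <- tbl$n_cnvrs[i]
    if (n == 0) next
    total <- tbl$cnvr_bp[i]
    base <- floor(total / n)
    sizes <- c(rep(base, n - 1), total - base * (n - 1))
    stopifnot(all(sizes >= 1), sum(sizes) == total)
    starts <- 1 + cumsum(c(0, head(sizes, -1) + gap))
    ends <- starts + sizes - 1
    if (max(ends) > tbl$chrom_bp[i]) {
      abort_bad_arg(paste0("chromosome ", tbl$chrom[i],
                           " too short for its synthetic intervals"))
    }
    cnvr_rows[[i]] <- tibble(chrom = tbl$chrom[i], start = starts, end = ends,
                             status = "loss")
    ng <- tbl$n_genes[i]
    if (ng > 0) {
      pos <- starts[1] + seq_len(ng) - 1
      gene_rows[[i]] <- tibble(
        gene_id = sprintf("%s_gene%03d", tbl$chrom[i], seq_len(ng)),
        chrom = tbl$chrom[i], start = pos, end = pos,
        biotype = NA_character_
      )
    }
  }
  cnvrs <- dplyr::bind_rows(cnvr_rows) |>
    mutate(cnvr_id = sprintf("CNVR%04d", dplyr::row_number()), .before = 1)
  list(
    cnvrs = cnvrs,
    genome = genome_spec(tbl$chrom, tbl$chrom_bp),
    annotation = dplyr::bind_rows(gene_rows)
  )
}

#' Build synthetic CNVRs matching a status summary table
#'
#' One dummy chromosome per status, holding `n_cnvrs` disjoint intervals whose
#' lengths sum to `total_bp`. [status_summary()] on the result must reproduce
#' the table's mean sizes and length shares exactly.
#'
#' @param tbl The `status` tibble from [horse_summary_tables()].
#' @return A CNVR-shaped tibble with `cnvr_id`, `chrom`, `start`, `end`,
#'   `status`.
#' @export
synthetic_cnvrs_from_status <- function(tbl) {
  rows <- purrr::pmap(tbl, function(status, n_cnvrs, total_bp) {
    base <- floor(total_bp / n_cnvrs)
    sizes <- c(rep(base, n_cnvrs - 1), total_bp - base * (n_cnvrs - 1))
    starts <- 1 + cumsum(c(0, head(sizes, -1) + 10000))
    tibble(chrom = paste0("chr_", status), start = starts,
           end = starts + sizes - 1, status = status)
  })
  dplyr::bind_rows(rows) |>
    mutate(cnvr_id = sprintf("CNVR%04d", dplyr::row_number()), .before = 1)
}
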