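# Native interchange is TSV with a header row and 1-based inclusive
# coordinates; BED is used only at the boundary (0-based half-open).

read_tsv_quiet <- function(path, col_types) {
  out <- tryCatch(
    # readr warns about parser/column mismatches; missing columns are raised
    # as structured errors by require_cols() instead
    suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                     progress = FALSE)),
    error = function(e) {
      stop("malformed file ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    stop("malformed file ", path, ": line ", prob$row[1] + 1L, ", ",
         prob$expected[1], " expected but got '", prob$actual[1], "'",
         call. = FALSE)
  }
  out
}

require_cols <- function(tbl, cols, path) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    stop("malformed file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Read and write the pipeline's tabular formats
#'
#' All tabular artifacts round-trip as TSV with a header and 1-based inclusive
#' coordinates: probe designs (`probe_id`, `chrom`, `start`, `end`, `row`,
#' `col`), intensities (`probe_id`, `test_intensity`, `ref_intensity`; grid
#' positions are restored by joining the design), planted-CNV truth sets
#' (`chrom`, `start`, `end`, `copies`), log2-ratio tracks (`chrom`,
#' `probe_id`, `midpoint`, `log2_ratio`), segments (`chrom`, `start`, `end`,
#' `n_probes`, `mean_log2`) and CNV calls (segment columns plus `sample_id`
#' and `status`). Malformed files error with the file, line and violated rule.
#'
#' @param x The object to write.
#' @param path File path.
#' @param design A probe design used to restore grid positions or validate
#'   alignment.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name cgh_io
NULL

#' @rdname cgh_io
#' @export
write_design_tsv <- function(x, path) {
  readr::write_tsv(x |> select("probe_id", "chrom", "start", "end", "row", "col"),
                   path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_design_tsv <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(
    probe_id = "c", chrom = "c", start = "d", end = "d",
    row = "i", col = "i"
  )) |> require_cols(c("probe_id", "chrom", "start", "end", "row", "col"), path)
  if (any(out$end < out$start)) {
    stop("malformed file ", path, ": end < start at line ",
         which(out$end < out$start)[1] + 1L, call. = FALSE)
  }
  out
}

#' @rdname cgh_io
#' @export
write_intensities_tsv <- function(x, path) {
  readr::write_tsv(x |> select("probe_id", "test_intensity", "ref_intensity"),
                   path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_intensities_tsv <- function(path, design = NULL) {
  out <- read_tsv_quiet(path, readr::cols(
    probe_id = "c", test_intensity = "d", ref_intensity = "d"
  )) |> require_cols(c("probe_id", "test_intensity", "ref_intensity"), path)
  if (any(out$test_intensity <= 0) || any(out$ref_intensity <= 0)) {
    stop("malformed file ", path, ": non-positive intensity", call. = FALSE)
  }
  if (!is.null(design)) {
    if (!identical(out$probe_id, design$probe_id)) {
      stop("malformed file ", path, ": probes not aligned to the design",
           call. = FALSE)
    }
    out <- out |> mutate(row = design$row, col = design$col)
  }
  out
}

#' @rdname cgh_io
#' @export
write_truth_tsv <- function(x, path) {
  readr::write_tsv(x |> select("chrom", "start", "end", "copies"), path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_truth_tsv <- function(path) {
  read_tsv_quiet(path, readr::cols(chrom = "c", start = "d", end = "d",
                                   copies = "i")) |>
    require_cols(c("chrom", "start", "end", "copies"), path)
}

#' @rdname cgh_io
#' @export
write_track_tsv <- function(x, path) {
  readr::write_tsv(x |> select("chrom", "probe_id", "midpoint", "log2_ratio"),
                   path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_track_tsv <- function(path) {
  read_tsv_quiet(path, readr::cols(chrom = "c", probe_id = "c",
                                   midpoint = "d", log2_ratio = "d")) |>
    require_cols(c("chrom", "probe_id", "midpoint", "log2_ratio"), path)
}

#' @rdname cgh_io
#' @export
write_segments_tsv <- function(x, path) {
  segs <- if (inherits(x, "cgh_segmentation")) x$segments else x
  readr::write_tsv(segs |> select("chrom", "start", "end", "n_probes",
                                  "mean_log2"), path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_segments_tsv <- function(path) {
  read_tsv_quiet(path, readr::cols(chrom = "c", start = "d", end = "d",
                                   n_probes = "i", mean_log2 = "d")) |>
    require_cols(c("chrom", "start", "end", "n_probes", "mean_log2"), path)
}

#' @rdname cgh_io
#' @export
write_calls_tsv <- function(x, path) {
  readr::write_tsv(x |> select("sample_id", "chrom", "start", "end", "status",
                               "mean_log2", "n_probes"), path)
  invisible(path)
}

#' @rdname cgh_io
#' @export
read_calls_tsv <- function(path) {
  read_tsv_quiet(path, readr::cols(sample_id = "c", chrom = "c", start = "d",
                                   end = "d", status = "c", mean_log2 = "d",
                                   n_probes = "i")) |>
    require_cols(c("sample_id", "chrom", "start", "end", "status",
                   "mean_log2", "n_probes"), path)
}

#' Convert between 1-based inclusive and BED (0-based half-open) coordinates
#'
#' The pipeline's native tables are 1-based inclusive; BED files are 0-based
#' half-open. These converters are exact inverses of each other.
#'
#' @param tbl A tibble with `start` and `end` columns.
#' @return The tibble with converted coordinates.
#' @export
to_bed_coords <- function(tbl) {
  tbl |> mutate(start = .data$start - 1)
}

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(tbl) {
  tbl |> mutate(start = .data$start + 1)
}

#' Export intervals as BED
#'
#' Writes calls or CNVRs as BED (0-based half-open). For CNV calls and CNVRs
#' the name field is the status and the score is `round(1000 * |mean_log2|)`
#' when a `mean_log2` column is present, else 0.
#'
#' @param x An interval tibble (`chrom`, `start`, `end`, optionally `status`,
#'   `mean_log2`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("status" %in% names(x)) x$status else rep(".", nrow(x))
  score <- if ("mean_log2" %in% names(x)) {
    pmin(1000, round(1000 * abs(x$mean_log2)))
  } else {
    rep(0, nrow(x))
  }
  bed <- tibble(chrom = x$chrom, start = x$start - 1, end = x$end,
                name = name, score = score)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' Returns 1-based inclusive coordinates; a 4th BED column is kept as `name`.
#'
#' @param path A BED file (3+ columns, no header).
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   stop("malformed file ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Read a gene annotation from BED or GFF3
#'
#' BED files are taken as one gene per line (the name column supplies
#' `gene_id`). GFF3 files are filtered to `type == "gene"`; `gene_id` comes
#' from the `ID` (or `Name`) attribute and `biotype` from `gene_biotype` /
#' `biotype` when present.
#'
#' @param path Annotation file; format chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`).
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `biotype` (1-based
#'   inclusive coordinates).
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    out <- read_bed(path)
    if (!"name" %in% names(out)) {
      stop("malformed file ", path, ": BED gene annotation needs a name column",
           call. = FALSE)
    }
    return(out |>
             mutate(gene_id = .data$name, biotype = NA_character_) |>
             select("gene_id", "chrom", "start", "end", "biotype"))
  }
  if (ext %in% c("gff", "gff3")) {
    gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                   error = function(e) {
                     stop("malformed file ", path, ": ", conditionMessage(e),
                          call. = FALSE)
                   })
    gr <- gr[gr$type == "gene"]
    meta <- as.data.frame(S4Vectors::mcols(gr))
    gene_id <- if ("ID" %in% names(meta)) as.character(meta$ID) else
      as.character(meta$Name)
    biotype <- if ("gene_biotype" %in% names(meta)) {
      as.character(meta$gene_biotype)
    } else if ("biotype" %in% names(meta)) {
      as.character(meta$biotype)
    } else {
      NA_character_
    }
    return(tibble(
      gene_id = gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      biotype = biotype
    ))
  }
  stop("unsupported annotation format: ", path, call. = FALSE)
}

#' @rdname cgh_io
#' @export
read_ct_table <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(sample_id = "c", assay_id = "c",
                                          role = "c", ct1 = "d", ct2 = "d",
                                          ct3 = "d")) |>
    require_cols(c("sample_id", "assay_id", "role", "ct1", "ct2", "ct3"), path)
  bad <- which(!out$role %in% c("target", "refgene"))
  if (length(bad) > 0) {
    stop("malformed file ", path, ": line ", bad[1] + 1L,
         ", role must be 'target' or 'refgene'", call. = FALSE)
  }
  out
}
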