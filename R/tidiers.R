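#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-sequence segmentation fit
#'
#' @param x A `cgh_dp_fit` from [dp_segment()].
#' @param ... Unused.
#' @return A tibble with one row per segment: `first`, `last`, `n_probes`,
#'   `mean`.
#' @exportS3Method generics::tidy
tidy.cgh_dp_fit <- function(x, ...) {
  x$segments
}

#' @rdname tidy.cgh_dp_fit
#' @return For `glance()`: a one-row tibble with `n`, `chosen_k`, `sse`,
#'   `penalty_lambda`.
#' @exportS3Method generics::glance
glance.cgh_dp_fit <- function(x, ...) {
  tibble(n = x$n, chosen_k = x$chosen_k, sse = x$sse_by_k[x$chosen_k],
         penalty_lambda = x$penalty_lambda)
}

#' Tidy a per-chromosome track segmentation
#'
#' @param x A `cgh_segmentation` from [segment_track()].
#' @param ... Unused.
#' @return A tibble with one row per segment across chromosomes.
#' @exportS3Method generics::tidy
tidy.cgh_segmentation <- function(x, ...) {
  x$segments
}

#' @rdname tidy.cgh_segmentation
#' @return For `glance()`: one row per chromosome with probe count, segment
#'   budget, chosen segment count, penalty and optimal cost.
#' @exportS3Method generics::glance
glance.cgh_segmentation <- function(x, ...) {
  x$by_chrom |> select(-"sse_by_k")
}
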