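#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats loess loess.control mad median predict quantile rnorm
#'   runif sd splinefun
#' @importFrom utils head tail
#' @useDynLib cghcnv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Round half away from zero to `digits` decimals. Base round() rounds half to
# even; published summary tables use conventional half-up rounding, so table
# reproduction requires it (e.g. 4.835 -> 4.84).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y")
}

abort_bad_arg <- function(msg) {
  stop(msg, call. = FALSE)
}
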