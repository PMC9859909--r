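#' Analysis thresholds
#'
#' Bundle of the filtering and windowing constants used throughout the
#' pipeline. Defaults are the full-genome values: alignments above 90%
#' identity, synteny blocks longer than 100 kb, internal breakpoints defined
#' as lying more than 1 Mb from chromosome ends, breakpoint regions
#' standardized to 100 kb, two 50-kb query-side windows, a 250-kb terminal
#' zone for the telomere screen, and 100,000 resampling iterations. All
#' base-pair thresholds are multiplied by `scale_factor`, so the same ratios
#' can be applied to small simulated genomes (e.g. `scale_factor = 1/100`
#' for 100-kb chromosomes standing in for ~10-Mb ones).
#'
#' Threshold comparisons are strict (`> min_identity`, `> min_block`).
#'
#' @param min_identity Minimum percent identity, exclusive. Default 90.
#' @param min_block Minimum synteny-block span on the reference, bp,
#'   exclusive. Default 100000.
#' @param internal_cutoff Distance from both scaffold ends beyond which a
#'   query-side breakpoint is considered internal and excluded from
#'   composition windows, bp. Default 1e6.
#' @param breakpoint_window Standardized breakpoint window size, bp.
#'   Default 1e5.
#' @param query_window Query-side window size, bp. Default 5e4.
#' @param telomeric_region Terminal zone used for the telomeric LINE screen
#'   and ancestral chromosome-end accounting, bp. Default 2.5e5.
#' @param resample_iterations Resampling iterations for enrichment tests.
#'   Default 1e5.
#' @param overlap_tolerance Symmetric padding when intersecting breakpoint
#'   intervals across species. Default `breakpoint_window / 2`.
#' @param scale_factor Multiplier applied to every bp threshold. Default 1.
#' @return A list of class `karyo_thresholds`.
#' @examples
#' thresholds(scale_factor = 1 / 100)$min_block  # 1000
#' @export
thresholds <- function(min_identity = 90,
                       min_block = 1e5,
                       internal_cutoff = 1e6,
                       breakpoint_window = 1e5,
                       query_window = 5e4,
                       telomeric_region = 2.5e5,
                       resample_iterations = 1e5,
                       overlap_tolerance = breakpoint_window / 2,
                       scale_factor = 1) {
  if (min_identity <= 0 || min_identity >= 100) {
    ks_abort("min_identity must be in (0, 100)", "configuration_error")
  }
  bp <- list(
    min_block = min_block, internal_cutoff = internal_cutoff,
    breakpoint_window = breakpoint_window, query_window = query_window,
    telomeric_region = telomeric_region, overlap_tolerance = overlap_tolerance
  )
  if (any(unlist(bp) <= 0) || resample_iterations < 1 || scale_factor <= 0) {
    ks_abort("all thresholds must be positive", "configuration_error")
  }
  out <- c(
    list(min_identity = min_identity),
    lapply(bp, function(v) v * scale_factor),
    list(resample_iterations = resample_iterations, scale_factor = scale_factor)
  )
  structure(out, class = "karyo_thresholds")
}
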