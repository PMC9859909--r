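# Linkage-map post-processing: marker binning, sex assignment from
# normalized coverage, genetic-vs-physical collinearity, and per-family
# karyotype signatures (segregating fusions/fissions).

#' Bin linkage-map markers along the physical assembly
#'
#' Markers are grouped per scaffold into `bin_size` windows
#' (`floor(bp / bin_size)`); each bin keeps one representative marker (the
#' smallest physical position) and sums SNP counts. Bins with more than
#' `max_snps_per_bin` SNPs are removed.
#'
#' @param markers Tibble with at least `scaffold` and `bp`; optional
#'   `snp_count` (default 1 per marker); other columns (family, linkage
#'   group, cM) are carried through from the representative marker.
#' @param bin_size Bin width, bp. Default 10000.
#' @param max_snps_per_bin Bins with more SNPs than this are dropped.
#'   Default 5.
#' @return Binned marker tibble with a `snp_count` column per bin.
#' @examples
#' m <- tibble::tibble(scaffold = "s1", bp = c(1000, 9999, 10001))
#' nrow(bin_markers(m))  # 2
#' @export
bin_markers <- function(markers, bin_size = 10000, max_snps_per_bin = 5) {
  assert_cols(markers, c("scaffold", "bp"), "markers")
  if (bin_size <= 0) ks_abort("bin_size must be positive",
                              "configuration_error")
  m <- markers
  if (!"snp_count" %in% names(m)) m$snp_count <- 1L
  group_cols <- intersect(c("family", "lg"), names(m))
  m$._bin <- floor(m$bp / bin_size)
  out <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(group_cols, "scaffold", "._bin")))) |>
    dplyr::arrange(bp, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(-dplyr::any_of(c("bp", "snp_count")), dplyr::first),
      bp = min(bp), snp_count = sum(snp_count), .groups = "drop"
    ) |>
    dplyr::filter(snp_count <= max_snps_per_bin) |>
    dplyr::select(-"._bin")
  out[do.call(order, out[intersect(c("family", "lg", "scaffold", "bp"),
                                   names(out))]), , drop = FALSE]
}

#' Assign offspring sex from normalized Z-chromosome coverage
#'
#' In a female-heterogametic system, females are hemizygous for the Z:
#' an individual is called female when its normalized coverage (scaffold
#' mean over individual mean) is strictly below `threshold` on every listed
#' Z scaffold, and male otherwise.
#'
#' @param coverage Tibble: `individual`, `scaffold`,
#'   `norm_cov` (normalized coverage).
#' @param z_scaffolds Character vector of Z-linked scaffold names.
#' @param threshold Hemizygosity threshold on normalized coverage.
#'   Default 0.75.
#' @return Tibble: `individual`, `sex` (`"F"`/`"M"`), one Z-coverage column
#'   per Z scaffold.
#' @export
assign_sex_by_coverage <- function(coverage, z_scaffolds, threshold = 0.75) {
  assert_cols(coverage, c("individual", "scaffold", "norm_cov"), "coverage")
  z <- coverage[coverage$scaffold %in% z_scaffolds, , drop = FALSE]
  have <- z |>
    dplyr::group_by(individual) |>
    dplyr::summarise(n = dplyr::n_distinct(scaffold), .groups = "drop")
  if (nrow(have) < dplyr::n_distinct(coverage$individual) ||
      any(have$n < length(z_scaffolds))) {
    ks_abort("missing Z-scaffold coverage for at least one individual",
             "input_error")
  }
  z |>
    dplyr::group_by(individual) |>
    dplyr::summarise(
      sex = if (all(norm_cov < threshold)) "F" else "M",
      .groups = "drop"
    ) |>
    dplyr::left_join(
      tidyr::pivot_wider(z, names_from = scaffold, values_from = norm_cov),
      by = "individual"
    )
}

#' Collinearity of genetic and physical maps
#'
#' Spearman's rank correlation between genetic position (cM order) and
#' physical position per (linkage group, scaffold) pair. The sign of rho is
#' arbitrary (a linkage group has no inherent orientation), so the absolute
#' value is reported alongside it. Runs of markers discordant with the
#' majority orientation are flagged as candidate inversions.
#'
#' @param markers Tibble: `lg`, `scaffold`, `cm`, `bp` (optionally
#'   `family`, carried through).
#' @param min_markers Minimum shared markers for a correlation; smaller
#'   pairs get `NA` rho and `insufficient_data = TRUE` (no error).
#' @param min_run Minimum length of a discordant run to flag.
#' @return Tibble per (lg, scaffold): `n_markers`, `rho`, `abs_rho`,
#'   `insufficient_data`, `n_discordant`, `discordant_runs` (list column of
#'   bp ranges).
#' @export
collinearity <- function(markers, min_markers = 3, min_run = 2) {
  assert_cols(markers, c("lg", "scaffold", "cm", "bp"), "markers")
  group_cols <- intersect(c("family", "lg", "scaffold"), names(markers))
  split_df <- split(markers,
                    lapply(group_cols, function(cc) markers[[cc]]),
                    drop = TRUE)
  out <- lapply(split_df, function(d) {
    base <- d[1, group_cols, drop = FALSE]
    base$n_markers <- nrow(d)
    if (nrow(d) < min_markers) {
      base$rho <- NA_real_; base$abs_rho <- NA_real_
      base$insufficient_data <- TRUE
      base$n_discordant <- NA_integer_
      base$discordant_runs <- list(tibble(start = double(), end = double()))
      return(base)
    }
    d <- d[order(d$cm, d$bp), , drop = FALSE]
    rho <- stats::cor(d$cm, d$bp, method = "spearman")
    orient <- if (rho >= 0) 1 else -1
    rb <- rank(orient * d$bp)
    disc <- rb != seq_along(rb)
    runs <- rle(disc)
    run_ends <- cumsum(runs$lengths)
    run_starts <- run_ends - runs$lengths + 1L
    flag <- which(runs$values & runs$lengths >= min_run)
    dr <- if (length(flag) > 0L) {
      tibble(start = d$bp[run_starts[flag]], end = d$bp[run_ends[flag]])
    } else {
      tibble(start = double(), end = double())
    }
    base$rho <- rho
    base$abs_rho <- abs(rho)
    base$insufficient_data <- FALSE
    base$n_discordant <- sum(disc)
    base$discordant_runs <- list(dr)
    base
  })
  dplyr::bind_rows(out)
}

#' Per-family karyotype signatures from a linkage map
#'
#' Emits a fusion signature when one linkage group carries at least
#' `min_markers` markers from each of two or more assembly scaffolds (the
#' family's chromosome is a fusion of those scaffolds), and a fission
#' signature when one scaffold's markers split across two or more linkage
#' groups with at least `min_markers` each. Families collinear with the
#' assembly produce no signatures.
#'
#' @param markers Binned marker tibble: `family`, `lg`, `scaffold` (and
#'   anything else).
#' @param min_markers Markers required per (linkage group, scaffold) cell
#'   for it to count. Default 5.
#' @return Tibble: `family`, `type` (`fusion`/`fission`), `lg`
#'   (comma-separated linkage groups), `scaffolds` (comma-separated).
#' @export
karyotype_from_map <- function(markers, min_markers = 5) {
  assert_cols(markers, c("family", "lg", "scaffold"), "markers")
  counts <- markers |>
    dplyr::count(family, lg, scaffold, name = "n") |>
    dplyr::filter(n >= min_markers)
  fusions <- counts |>
    dplyr::group_by(family, lg) |>
    dplyr::filter(dplyr::n_distinct(scaffold) >= 2L) |>
    dplyr::summarise(scaffolds = paste(sort(unique(scaffold)),
                                       collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(type = "fusion", lg = as.character(lg))
  fissions <- counts |>
    dplyr::group_by(family, scaffold) |>
    dplyr::filter(dplyr::n_distinct(lg) >= 2L) |>
    dplyr::summarise(lg = paste(sort(unique(as.character(lg))),
                                collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(type = "fission", scaffolds = as.character(scaffold)) |>
    dplyr::select(-"scaffold")
  out <- dplyr::bind_rows(
    dplyr::select(fusions, family, type, lg, scaffolds),
    dplyr::select(fissions, family, type, lg, scaffolds)
  )
  out[order(out$family, out$type, out$lg), , drop = FALSE]
}
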