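#' Simulator configuration
#'
#' Parameters for the karyotype-evolution simulator. Defaults describe a
#' desk-scale genome: ~100-kb chromosomes standing in for ~10-Mb ones, with
#' every genomic distance 1/100 of its full-genome counterpart (use
#' `thresholds(scale_factor = 1/100)` downstream).
#'
#' @param n_chromosomes Number of ancestral chromosomes.
#' @param chromosome_length_mean,chromosome_length_sd Chromosome length
#'   distribution, bp (normal, truncated below at `4 * break_margin`).
#' @param element_densities Named numeric vector mapping element classes
#'   (CDS, LINE, SINE, LTR, DNA, RC) to target genome fractions in
#'   \[0, 1\]; their sum must be at most 1.
#' @param fusion_site_enrichment Named numeric vector of multiplicative
#'   placement-density factors (>= 0) applied within terminal zones of
#'   ancestral chromosomes. Fusions join chromosome ends, so these zones are
#'   the sequence that ends up flanking fusion junctions.
#' @param fusion_zone Length of each terminal enrichment zone, bp.
#' @param element_length_mean Mean element length, bp.
#' @param line_families Family labels cycled over LINE elements.
#' @param telomere_array_copies Tandem TTAGG copies written at flagged
#'   chromosome ends and retained fusion remnants.
#' @param telomere_retention_prob Probability that a fusion junction keeps a
#'   detectable internal telomere remnant.
#' @param telomere_line_family Optional LINE family placed exclusively in
#'   terminal `telomere_zone` regions (for the telomeric LINE screen);
#'   `NULL` disables it.
#' @param telomere_line_per_end Count of such elements per chromosome end.
#' @param telomere_zone Terminal zone length for `telomere_line_family`, bp.
#' @param alignment_fragmentation_mean Target length of emitted alignment
#'   pieces, bp.
#' @param singleton_noise_rate Expected spurious cross-chromosome alignment
#'   records per reference chromosome (Poisson).
#' @param singleton_noise_len Length of each spurious record, bp; keep it
#'   below the scaled `min_block` so noise is filterable.
#' @param break_margin No event breakpoint is placed within this distance of
#'   a chromosome end, bp.
#' @param min_event_spacing Minimum distance between any two event loci in
#'   ancestral coordinates, bp. Events closer than the classifier's overlap
#'   tolerance are unidentifiable by construction, so the simulator keeps
#'   loci separated; breakpoint reuse seen in real genomes is deliberately
#'   not emulated.
#' @param seed Integer seed; every simulator function derives its RNG stream
#'   from it, so identical configs give byte-identical output.
#' @return A validated list of class `karyo_sim_config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 5, seed = 1)
#' cfg$n_chromosomes
#' @export
sim_config <- function(n_chromosomes = 20,
                       chromosome_length_mean = 1e5,
                       chromosome_length_sd = 1.5e4,
                       element_densities = c(
                         CDS = 0.15, LINE = 0.12, SINE = 0.03,
                         LTR = 0.05, DNA = 0.08, RC = 0.02
                       ),
                       fusion_site_enrichment = NULL,
                       fusion_zone = 1000,
                       element_length_mean = 50,
                       line_families = paste0("LINE-fam", 1:4),
                       telomere_array_copies = 20,
                       telomere_retention_prob = 1,
                       telomere_line_family = NULL,
                       telomere_line_per_end = 0,
                       telomere_zone = 2500,
                       alignment_fragmentation_mean = 5000,
                       singleton_noise_rate = 2,
                       singleton_noise_len = 500,
                       break_margin = 5000,
                       min_event_spacing = 2000,
                       seed = 1L) {
  dens <- element_densities %||% numeric()
  if (length(dens) > 0 && (any(dens < 0) || any(dens > 1) || sum(dens) > 1)) {
    ks_abort("element densities must lie in [0, 1] and sum to at most 1",
             "configuration_error")
  }
  enr <- fusion_site_enrichment %||% numeric()
  if (length(enr) > 0 && any(enr < 0)) {
    ks_abort("fusion_site_enrichment factors must be >= 0",
             "configuration_error")
  }
  lens <- c(chromosome_length_mean, element_length_mean,
            alignment_fragmentation_mean, fusion_zone, telomere_zone,
            break_margin, min_event_spacing, singleton_noise_len)
  if (any(lens <= 0) || n_chromosomes < 1 || chromosome_length_sd < 0) {
    ks_abort("lengths and counts must be positive", "configuration_error")
  }
  if (telomere_retention_prob < 0 || telomere_retention_prob > 1) {
    ks_abort("telomere_retention_prob must be in [0, 1]",
             "configuration_error")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_mean = chromosome_length_mean,
    chromosome_length_sd = chromosome_length_sd,
    element_densities = dens,
    fusion_site_enrichment = enr,
    fusion_zone = fusion_zone,
    element_length_mean = element_length_mean,
    line_families = line_families,
    telomere_array_copies = as.integer(telomere_array_copies),
    telomere_retention_prob = telomere_retention_prob,
    telomere_line_family = telomere_line_family,
    telomere_line_per_end = as.integer(telomere_line_per_end),
    telomere_zone = telomere_zone,
    alignment_fragmentation_mean = alignment_fragmentation_mean,
    singleton_noise_rate = singleton_noise_rate,
    singleton_noise_len = singleton_noise_len,
    break_margin = break_margin,
    min_event_spacing = min_event_spacing,
    seed = as.integer(seed)
  ), class = "karyo_sim_config")
}

#' Write or read a simulator configuration as YAML
#'
#' @param config A `karyo_sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `karyo_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$element_densities <- as.list(x$element_densities)
  x$fusion_site_enrichment <- as.list(x$fusion_site_enrichment)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$element_densities <- unlist(x$element_densities) %||% NULL
  x$fusion_site_enrichment <- unlist(x$fusion_site_enrichment) %||% NULL
  do.call(sim_config, x)
}
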