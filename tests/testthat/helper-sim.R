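# Shared fixtures: small configs, desk-scale thresholds, and hand-rolled
# builders for alignment/block tables used across tests.

th_desk <- function(...) thresholds(scale_factor = 1 / 100, ...)

quiet_cfg <- function(seed = 1, n = 10, ...) {
  sim_config(n_chromosomes = n, element_densities = NULL,
             singleton_noise_rate = 0, seed = seed, ...)
}

# One alignment record with sensible defaults.
aln_row <- function(ref = "r1", rs = 0, re = 1000, query = "q1",
                    qs = rs, qe = re, identity = 95, strand = "+") {
  tibble::tibble(ref = ref, ref_start = rs, ref_end = re, query = query,
                 query_start = qs, query_end = qe, identity = identity,
                 strand = strand)
}

len_tbl <- function(...) {
  v <- c(...)
  tibble::tibble(chrom = names(v), length = unname(v))
}

# Brute-force covered-bp oracle: per-base counting.
bp_covered_brute <- function(track, chrom, start, end) {
  pos <- seq(start, end - 1)
  covered <- rep(FALSE, length(pos))
  tr <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    covered <- covered | (pos >= tr$start[i] & pos < tr$end[i])
  }
  sum(covered)
}
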