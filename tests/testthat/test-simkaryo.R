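# Simulator: ancestral genome, karyotype evolution, emission.

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(element_densities = c(LINE = 0.7, CDS = 0.4)),
               class = "configuration_error")
  expect_error(sim_config(chromosome_length_mean = -1),
               class = "configuration_error")
  expect_error(sim_config(telomere_retention_prob = 1.2),
               class = "configuration_error")
  expect_error(simulate_ancestral_genome(list()),
               class = "configuration_error")
})

test_that("degenerate single-chromosome genome has one segment and telomeres", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length_mean = 1e5,
                    chromosome_length_sd = 0, element_densities = NULL,
                    seed = 1)
  g <- simulate_ancestral_genome(cfg)
  expect_equal(nrow(g$chrom_lengths), 1L)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(g$segments$anc_start, 0)
  expect_equal(g$segments$anc_end, g$chrom_lengths$length)
  expect_true(all(g$telomeres$left) && all(g$telomeres$right))
})

test_that("realized element fraction hits its target within 20% relative", {
  cfg <- sim_config(n_chromosomes = 20, element_densities = c(LINE = 0.30),
                    seed = 11)
  g <- simulate_ancestral_genome(cfg)
  tr <- element_track(g)
  frac <- sum(tr$end[tr$class == "LINE"] - tr$start[tr$class == "LINE"]) /
    sum(g$chrom_lengths$length)
  expect_gt(frac, 0.24)
  expect_lt(frac, 0.36)
})

test_that("identical seeds give identical genomes, different seeds differ", {
  g1 <- simulate_ancestral_genome(sim_config(n_chromosomes = 6, seed = 5))
  g2 <- simulate_ancestral_genome(sim_config(n_chromosomes = 6, seed = 5))
  g3 <- simulate_ancestral_genome(sim_config(n_chromosomes = 6, seed = 6))
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$anc_elements, g2$anc_elements)
  expect_false(identical(g1$anc_elements, g3$anc_elements))
})

test_that("zero events reproduce the ancestral genome at every tip", {
  cfg <- quiet_cfg(seed = 2)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = character()), cfg)
  for (tip in sim$tips) {
    expect_identical(tip$segments, anc$segments)
  }
  expect_equal(nrow(sim$log), 0L)
})

test_that("chromosome counts follow fissions minus fusions along each path", {
  cfg <- quiet_cfg(seed = 3, n = 10)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = "sister", fusions = 3),
                          cfg)
  expect_equal(nrow(sim$tips$sister$chrom_lengths), 7L)
  expect_equal(sum(sim$tips$sister$chrom_lengths$length),
               sum(anc$chrom_lengths$length))
  expect_equal(nrow(sim$tips$pop1$chrom_lengths), 10L)

  ev <- data.frame(branch = c("ingroup_stem", "pop1", "pop2"),
                   fissions = c(2, 1, 0), fusions = c(1, 0, 2))
  sim2 <- evolve_karyotype(anc, ev, cfg)
  expect_equal(nrow(sim2$tips$pop1$chrom_lengths), 10L + 2 - 1 + 1)
  expect_equal(nrow(sim2$tips$pop2$chrom_lengths), 10L + 2 - 1 - 2)
  expect_equal(nrow(sim2$tips$outgroup$chrom_lengths), 10L)
})

test_that("fission then re-fusion in original orientation restores segments", {
  cfg <- quiet_cfg(seed = 4, n = 3)
  g <- simulate_ancestral_genome(cfg)
  before <- g$segments
  g2 <- karyoshift:::do_fission(g, chrom = 2, pos = 40000)
  expect_equal(nrow(g2$chrom_lengths), 4L)
  new_ids <- setdiff(g2$chrom_lengths$chrom, g$chrom_lengths$chrom)
  g3 <- karyoshift:::do_fusion(g2, new_ids[1], "right", new_ids[2], "left",
                               retain = FALSE)
  restored <- g3$segments[g3$segments$chrom == max(g3$segments$chrom), ]
  orig <- before[before$chrom == 2, ]
  expect_equal(restored$anc_chrom, rep(orig$anc_chrom, 2)[1:2])
  expect_equal(min(restored$anc_start), orig$anc_start)
  expect_equal(max(restored$anc_end), orig$anc_end)
  expect_equal(restored$start, c(0, 40000))
  expect_true(all(restored$strand == 1L))
})

test_that("infeasible event requests raise simulation errors naming the branch", {
  cfg <- quiet_cfg(seed = 5, n = 2)
  anc <- simulate_ancestral_genome(cfg)
  expect_error(
    evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 2), cfg),
    regexp = "pop1", class = "simulation_error")
  expect_error(
    evolve_karyotype(anc, data.frame(branch = "nope", fusions = 1), cfg),
    class = "simulation_error")
})

test_that("self-alignment tiles every chromosome against its own name", {
  cfg <- quiet_cfg(seed = 6, n = 4)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 1), cfg)
  g <- sim$tips$pop1
  aln <- emit_alignments(g, g, cfg)
  expect_true(all(aln$ref == aln$query))
  expect_true(all(aln$identity > 90 & aln$identity <= 100))
  cov <- aln |>
    dplyr::group_by(ref) |>
    dplyr::summarise(bp = sum(ref_end - ref_start))
  lens <- chromosome_lengths(g)
  expect_equal(cov$bp[match(lens$chrom, cov$ref)], lens$length)
  bp <- call_breakpoints(build_blocks(aln, th_desk()), lens)
  expect_equal(nrow(bp), 0L)
})

test_that("genomes from different ancestors cannot be aligned", {
  a <- simulate_ancestral_genome(quiet_cfg(seed = 7, n = 3))
  b <- simulate_ancestral_genome(quiet_cfg(seed = 8, n = 3))
  expect_error(emit_alignments(a, b, quiet_cfg(seed = 7, n = 3)),
               class = "lineage_error")
})

test_that("a single query fusion yields exactly one breakpoint downstream", {
  cfg <- quiet_cfg(seed = 9, n = 6)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 1), cfg)
  aln <- emit_alignments(sim$tips$pop1, sim$tips$outgroup, cfg)
  bl <- build_blocks(aln, th_desk())
  bp <- call_breakpoints(bl, chromosome_lengths(sim$tips$pop1))
  expect_equal(nrow(bp), 1L)
  fused <- max(sim$tips$pop1$segments$chrom)
  expect_equal(bp$ref, paste0("pop1_chr", fused))
})

test_that("singleton noise does not change the filtered block set", {
  base <- sim_config(n_chromosomes = 8, element_densities = NULL,
                     singleton_noise_rate = 0, seed = 10)
  noisy <- sim_config(n_chromosomes = 8, element_densities = NULL,
                      singleton_noise_rate = 5, seed = 10)
  anc <- simulate_ancestral_genome(base)
  ev <- data.frame(branch = c("pop1", "sister"), fissions = c(1, 1),
                   fusions = c(1, 1))
  s0 <- evolve_karyotype(anc, ev, base)
  s5 <- evolve_karyotype(anc, ev, noisy)
  th <- th_desk()
  b0 <- build_blocks(emit_alignments(s0$tips$pop1, s0$tips$sister, base), th)
  b5 <- build_blocks(emit_alignments(s5$tips$pop1, s5$tips$sister, noisy), th)
  cols <- c("ref", "ref_start", "ref_end", "query")
  expect_equal(as.data.frame(b0[cols]), as.data.frame(b5[cols]))
})

test_that("emitted FASTA carries telomere arrays where flags are true", {
  cfg <- sim_config(n_chromosomes = 3, element_densities = c(LINE = 0.05),
                    telomere_array_copies = 10, singleton_noise_rate = 0,
                    seed = 12)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 1), cfg)
  g <- sim$tips$pop1
  dir <- withr::local_tempdir()
  paths <- emit_annotations_and_sequences(g, cfg, dir)
  seqs <- Biostrings::readDNAStringSet(paths[["fasta"]])
  lens <- chromosome_lengths(g)
  expect_equal(unname(Biostrings::width(seqs)[match(lens$chrom, names(seqs))]),
               lens$length)
  # every intact chromosome: CCTAA array at the left end, TTAGG at the right
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    ch <- as.integer(sub(".*_chr", "", nm))
    tl <- g$telomeres[g$telomeres$chrom == ch, ]
    s <- as.character(seqs[[i]])
    if (tl$left) expect_equal(substr(s, 1, 10), strrep("CCTAA", 2))
    if (tl$right) expect_equal(substr(s, nchar(s) - 9, nchar(s)),
                               strrep("TTAGG", 2))
  }
  # internal remnant at the logged fusion junction
  rp <- karyoshift:::remnant_positions(g)
  expect_equal(nrow(rp), 1L)
  s <- as.character(seqs[[paste0("pop1_chr", rp$chrom)]])
  win <- substr(s, rp$pos - 60, rp$pos + 60)
  expect_true(scan_telomeric_repeats(win)$present)
  # BED round-trips through the reader
  tr <- read_elements(paths[["elements"]])
  expect_equal(nrow(tr), nrow(element_track(g)))
  expect_true(all(tr$class == "LINE"))
  # lengths table matches
  expect_equal(read_lengths(paths[["lengths"]]), chromosome_lengths(g))
})

test_that("empty element map still writes headers and lengths", {
  cfg <- quiet_cfg(seed = 13, n = 2)
  g <- simulate_ancestral_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- emit_annotations_and_sequences(g, cfg, dir)
  expect_true(file.exists(paths[["lengths"]]))
  expect_equal(file.size(paths[["elements"]]), 0)
  expect_equal(nrow(read_lengths(paths[["lengths"]])), 2L)
})

test_that("sim config YAML round-trips", {
  cfg <- sim_config(n_chromosomes = 7, element_densities = c(LINE = 0.1),
                    fusion_site_enrichment = c(LINE = 5), seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$n_chromosomes, 7L)
  expect_equal(cfg2$element_densities, c(LINE = 0.1))
  expect_equal(cfg2$fusion_site_enrichment, c(LINE = 5))
  expect_equal(cfg2$seed, 99L)
})

test_that("ground-truth log round-trips through TSV", {
  cfg <- quiet_cfg(seed = 14, n = 8)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = c("pop1", "sister"),
                                          fissions = c(1, 2),
                                          fusions = c(2, 1)), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$log, f)
  log2 <- read_ground_truth(f)
  expect_equal(as.data.frame(log2), as.data.frame(sim$log))
  tips <- replay_log(anc, log2)
  expect_identical(tips$pop1$segments, sim$tips$pop1$segments)
})
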