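# Outgroup polarization, randomization test, telomere scanning.

test_that("overlap flags come from padded closed-interval intersection", {
  ev <- tibble::tibble(ref = "r1", start = c(100, 500, 900, 2000),
                       end = c(100, 500, 900, 2000))
  brk <- tibble::tibble(ref = "r1", start = c(90, 520, 905), end = c(95, 530, 906))
  out0 <- overlap_with_outgroup(ev, brk[0, ], tolerance = 50)
  expect_false(any(out0$overlap))
  out <- overlap_with_outgroup(ev, brk, tolerance = 20)
  expect_equal(out$overlap, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(out, "n_overlap"), 3L)
  expect_equal(attr(out, "n_total"), 4L)
  expect_error(
    overlap_with_outgroup(tibble::tibble(ref = "zz", start = 1, end = 2),
                          brk, 0, scaffold_lengths = len_tbl(r1 = 10000)),
    class = "input_error")
})

test_that("randomization p-value hits its analytic bounds", {
  lens <- len_tbl(s1 = 1000)
  bp <- tibble::tibble(ref = "s1", start = 100, end = 150)
  brk <- tibble::tibble(ref = "s1", start = 400, end = 410)
  r0 <- randomization_test(bp, lens, brk, n_iter = 200, seed = 1,
                           observed = 0)
  expect_equal(r0$p, 1)
  # breaks tiling the whole scaffold: every placement overlaps
  tile <- tibble::tibble(ref = "s1", start = 0, end = 1000)
  r1 <- randomization_test(bp, lens, tile, n_iter = 200, seed = 1)
  expect_equal(r1$observed, 1L)
  expect_equal(r1$p, 1)
  expect_error(randomization_test(bp[0, ], lens, brk), class = "input_error")
  expect_error(
    randomization_test(tibble::tibble(ref = "s1", start = 0, end = 5000),
                       lens, brk, n_iter = 10),
    class = "placement_error")
})

test_that("empirical p matches exhaustive enumeration on a discrete toy genome", {
  # 1 scaffold of 10 units, one 1-unit synteny break, one 1-unit breakpoint
  lens <- len_tbl(s1 = 10)
  brk <- tibble::tibble(ref = "s1", start = 4, end = 5)
  bp <- tibble::tibble(ref = "s1", start = 4, end = 5)
  # enumeration oracle: discrete starts 0..9, closed-interval overlap rule
  hits <- sum(vapply(0:9, function(x) (x <= 5) && (x + 1 >= 4), logical(1)))
  p_exact <- hits / 10 # P(count >= 1) for a single placement
  n_iter <- 10000
  r <- randomization_test(bp, lens, brk, n_iter = n_iter, seed = 42,
                          observed = 1)
  se <- sqrt(p_exact * (1 - p_exact) / n_iter)
  expect_lt(abs(r$p - p_exact), 3 * se + 1 / n_iter)
  expect_equal(glance(r)$p, r$p)
})

test_that("identical seeds reproduce the randomization test exactly", {
  lens <- len_tbl(s1 = 5000, s2 = 3000)
  brk <- tibble::tibble(ref = c("s1", "s2"), start = c(100, 2000),
                        end = c(200, 2100))
  bp <- tibble::tibble(ref = c("s1", "s1", "s2"),
                       start = c(50, 900, 1500), end = c(60, 950, 1600))
  r1 <- randomization_test(bp, lens, brk, n_iter = 500, seed = 9)
  r2 <- randomization_test(bp, lens, brk, n_iter = 500, seed = 9)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$p, r2$p)
})

test_that("telomeric repeat scanning finds tandem arrays on either strand", {
  expect_true(scan_telomeric_repeats(strrep("TTAGG", 10))$present)
  expect_equal(scan_telomeric_repeats(strrep("TTAGG", 10))$copies, 10L)
  s <- paste0(strrep("ACGT", 100), strrep("CCTAA", 6), strrep("TGCA", 100))
  r <- scan_telomeric_repeats(s)
  expect_true(r$present)
  expect_equal(r$motif, "CCTAA")
  # random sequence without motifs
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  expect_false(scan_telomeric_repeats(rnd)$present)
  # below the tandem-copy threshold
  expect_false(scan_telomeric_repeats(strrep("TTAGG", 4))$present)
  # N breaks a run
  broken <- paste0(strrep("TTAGG", 3), "N", strrep("TTAGG", 3))
  expect_false(scan_telomeric_repeats(broken)$present)
  expect_error(scan_telomeric_repeats("TTAGGX"), class = "sequence_error")
})

mk_events <- function(n, reference, event_type, shared_by) {
  tibble::tibble(
    reference = reference, event_type = event_type,
    shared_by = replicate(n, shared_by, simplify = FALSE)
  )
}

test_that("polarization rules resolve each evidence configuration", {
  tree <- karyo_tree()
  ev <- dplyr::bind_rows(
    mk_events(1, "pop1", "fusion", c("pop2", "sister", "outgroup")),
    mk_events(1, "pop1", "fission", "sister"),
    mk_events(1, "pop1", "shared_pair", c("outgroup", "sister")),
    mk_events(1, "pop1", "shared_pair", c("pop2", "sister")),
    mk_events(1, "pop1", "fusion", c("pop2", "sister", "outgroup")),
    mk_events(1, "pop1", "fusion", c("pop2", "sister", "outgroup"))
  )
  overlap <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  telomere <- c(NA, NA, NA, FALSE, TRUE, FALSE)
  pol <- polarize_events(ev, tree, overlap = overlap, telomere = telomere)
  e <- pol$events
  # (1) fusion + overlap: confirmed fusion in the reference
  expect_equal(e$final_type[1], "fusion")
  expect_equal(e$branch[1], "pop1")
  expect_equal(e$rule[1], 1L)
  # fission + no overlap: confirmed fission in the breaking query
  expect_equal(e$final_type[2], "fission")
  expect_equal(e$branch[2], "sister")
  # (4) shared pair + overlap: fusion in the joined lineages
  expect_equal(e$final_type[3], "fusion")
  expect_equal(e$branch[3], "pop_stem")
  expect_equal(e$rule[3], 4L)
  # (5) shared pair + no overlap + no repeats, breakers form no clade with
  # the reference joined set... breakers {pop2, sister} are not a clade
  expect_equal(e$final_type[4], "ambiguous")
  expect_equal(e$rule[4], 3L)
  # (2) fusion + no overlap + repeats: fusion back to the ancestral state
  expect_equal(e$final_type[5], "ancestral_fusion")
  expect_equal(e$rule[5], 2L)
  # (3) fusion + no overlap + no repeats, non-clade breakers: ambiguous
  expect_equal(e$final_type[6], "ambiguous")
  expect_equal(e$rule[6], 3L)
})

test_that("missing evidence yields unresolved calls, never guesses", {
  ev <- mk_events(2, "pop1", "shared_pair", c("outgroup", "sister"))
  pol <- polarize_events(ev, karyo_tree(), overlap = c(NA, FALSE),
                         telomere = c(NA, NA))
  expect_equal(pol$events$final_type, c("unresolved", "unresolved"))
})

test_that("all-fusion and zero-fusion edge cases give 100% and 0%", {
  ev <- mk_events(4, "pop1", "fusion", c("pop2", "sister", "outgroup"))
  pol <- polarize_events(ev, karyo_tree(), overlap = rep(TRUE, 4))
  expect_equal(pol$fusion_fraction, 100)
  ev2 <- mk_events(3, "pop1", "fission", "sister")
  pol2 <- polarize_events(ev2, karyo_tree(), overlap = rep(FALSE, 3))
  expect_equal(pol2$fusion_fraction, 0)
})

test_that("fusion fraction is invariant to event order", {
  ev <- dplyr::bind_rows(
    mk_events(5, "outgroup", "fusion", c("pop1", "pop2", "sister")),
    mk_events(4, "pop1", "fission", "outgroup")
  )
  ov <- c(rep(TRUE, 3), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 2))
  p1 <- polarize_events(ev, karyo_tree(), overlap = ov,
                        telomere = rep(FALSE, 9))
  idx <- rev(seq_len(9))
  p2 <- polarize_events(ev[idx, ], karyo_tree(), overlap = ov[idx],
                        telomere = rep(FALSE, 9))
  expect_equal(p1$fusion_fraction, p2$fusion_fraction)
})

test_that("a simulated ingroup fusion overlaps the outgroup synteny break", {
  cfg <- quiet_cfg(seed = 40, n = 6)
  anc <- simulate_ancestral_genome(cfg)
  sim <- evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 1), cfg)
  th <- th_desk()
  ref <- sim$tips$pop1
  brk <- outgroup_synteny_breaks(ref, anc, cfg, th)
  bp <- call_breakpoints(
    build_blocks(emit_alignments(ref, sim$tips$outgroup, cfg), th),
    chromosome_lengths(ref))
  out <- overlap_with_outgroup(bp, brk, th$overlap_tolerance)
  expect_true(all(out$overlap))
})
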