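# Breakpoint composition: track merging, window standardization,
# densities, resampling enrichment, BH, telomeric LINE screen.

test_that("element merging unions overlaps and validates intervals", {
  el <- tibble::tibble(chrom = "c1", start = c(0, 50, 300),
                       end = c(100, 150, 400), class = "LINE")
  m <- merge_elements(el)
  expect_equal(m$start, c(0, 300))
  expect_equal(m$end, c(150, 400))
  # disjoint intervals unchanged
  el2 <- tibble::tibble(chrom = "c1", start = c(0, 200), end = c(100, 300),
                        class = "DNA")
  expect_equal(merge_elements(el2)$start, c(0, 200))
  # empty in, empty out
  expect_equal(nrow(merge_elements(el[0, ])), 0L)
  expect_error(merge_elements(tibble::tibble(chrom = "c1", start = 10,
                                             end = 10, class = "RC")),
               class = "input_error")
})

test_that("family labels survive merging with boundary splits", {
  el <- tibble::tibble(chrom = "c1", start = c(0, 80), end = c(100, 200),
                       class = "LINE", family = c("famA", "famB"))
  m <- merge_elements(el)
  expect_equal(nrow(m), 2L)
  expect_equal(m$family, c("famA", "famB"))
  expect_equal(m$end[1], m$start[2]) # no double counting in the overlap
  expect_equal(max(m$end) - min(m$start), 200)
})

test_that("reference windows are centred on midpoints and clipped", {
  th <- thresholds() # 100-kb window
  ev <- tibble::tibble(ref = "s1", start = c(500000, 10000),
                       end = c(500000, 10000))
  w <- standardize_breakpoints(ev, len_tbl(s1 = 2e6), th, "reference")
  expect_equal(w$start[1], 450000)
  expect_equal(w$end[1], 550000)
  expect_equal(w$start[2], 0) # clipped at the scaffold start
  expect_error(standardize_breakpoints(ev, len_tbl(zz = 1), th, "reference"),
               class = "input_error")
})

test_that("query windows extend to the nearer end, clip to terminal windows, and drop internal breakpoints", {
  th <- thresholds() # 50-kb query windows, 1-Mb internal cutoff
  qlen <- len_tbl(q1 = 2e6, q2 = 2e6, q3 = 4e6)
  ev <- tibble::tibble(
    left_query = c("q1", "q3"), right_query = c("q2", "q3"),
    left_q_edge = c(1.98e6, 1.5e6), right_q_edge = c(120000, 2.5e6)
  )
  w <- standardize_breakpoints(ev, qlen, th, "query")
  # q1 edge 20 kb from the right end: terminal 50 kb selected
  expect_equal(w$start[w$chrom == "q1"], 2e6 - 50000)
  expect_equal(w$end[w$chrom == "q1"], 2e6)
  # q2 edge 120 kb from the left end: window extends toward that end
  expect_equal(w$start[w$chrom == "q2"], 70000)
  expect_equal(w$end[w$chrom == "q2"], 120000)
  # q3 edges are > 1 Mb from both ends: excluded as internal
  expect_false("q3" %in% w$chrom)
})

test_that("duplicate windows at one scaffold end collapse to the outermost", {
  th <- thresholds()
  qlen <- len_tbl(q1 = 2e6, q2 = 2e6)
  ev <- tibble::tibble(
    left_query = c("q1", "q1"), right_query = c("q2", "q2"),
    left_q_edge = c(1.95e6, 1.90e6), right_q_edge = c(NA, NA)
  )
  w <- standardize_breakpoints(ev, qlen, th, "query")
  expect_equal(nrow(w), 1L)
  expect_equal(w$end, 2e6) # the window closest to the end wins
})

test_that("ambiguous events are excluded from window sets", {
  th <- thresholds()
  ev <- tibble::tibble(ref = c("s1", "s1"), start = c(5e5, 8e5),
                       end = c(5e5, 8e5),
                       final_type = c("fusion", "ambiguous"))
  w <- standardize_breakpoints(ev, len_tbl(s1 = 2e6), th, "reference")
  expect_equal(nrow(w), 1L)
})

test_that("mean density is covered bp over window bp", {
  win <- tibble::tibble(chrom = "c1", start = c(0, 100), end = c(100, 200))
  tr <- tibble::tibble(chrom = "c1", start = c(10, 120), end = c(40, 170))
  expect_equal(mean_density(win, tr), (0.3 + 0.5) / 2)
  expect_equal(mean_density(win, tr[0, ]), 0)
  full <- tibble::tibble(chrom = "c1", start = 0, end = 200)
  expect_equal(mean_density(win, full), 1)
  expect_error(mean_density(win[0, ], tr), class = "input_error")
  expect_error(
    mean_density(tibble::tibble(chrom = "c1", start = 5, end = 5), tr),
    class = "input_error")
})

test_that("a saturated uniform track gives p = 1", {
  lens <- len_tbl(c1 = 100000)
  win <- tibble::tibble(chrom = "c1", start = c(10000, 50000),
                        end = c(11000, 51000))
  full <- tibble::tibble(chrom = "c1", start = 0, end = 100000)
  r <- resample_test(win, full, lens, n_iter = 200, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$observed, 1)
  expect_equal(r$null_mean, 1)
})

test_that("resampling is reproducible and respects the exclusion zone", {
  set.seed(77)
  lens <- len_tbl(c1 = 50000, c2 = 50000)
  tr <- tibble::tibble(chrom = sample(c("c1", "c2"), 300, TRUE),
                       start = round(runif(300, 0, 49000)))
  tr$end <- tr$start + 100
  win <- tibble::tibble(chrom = "c1", start = c(1000, 30000),
                        end = c(2000, 31000))
  r1 <- resample_test(win, tr, lens, n_iter = 300, seed = 5)
  r2 <- resample_test(win, tr, lens, n_iter = 300, seed = 5)
  expect_identical(r1$null_means, r2$null_means)
  expect_identical(r1$p, r2$p)
  # exclusion: leave no room outside the excluded region and expect failure
  big_excl <- tibble::tibble(chrom = c("c1", "c2"), start = c(0, 0),
                             end = c(50000, 50000))
  expect_error(
    resample_test(win, tr, lens, n_iter = 10, seed = 1, exclude = big_excl,
                  max_retry = 20),
    class = "placement_error")
})

test_that("per-class enrichment table carries BH-adjusted p-values", {
  cfg <- sim_config(n_chromosomes = 10,
                    element_densities = c(LINE = 0.1, CDS = 0.1),
                    singleton_noise_rate = 0, seed = 50)
  g <- simulate_ancestral_genome(cfg)
  tr <- element_track(g)
  lens <- chromosome_lengths(g)
  win <- tibble::tibble(chrom = lens$chrom[1:4], start = 20000, end = 21000)
  res <- breakpoint_enrichment(win, tr, lens, n_iter = 200, seed = 2,
                               set_type = "fusion-reference")
  expect_equal(nrow(res), 2L)
  expect_setequal(res$class, c("CDS", "LINE"))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(res$p_adj <= 1))
})

test_that("BH adjustment matches the printed worked example and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 0)), class = "input_error")
  expect_error(bh_adjust(c(0.1, 1.4)), class = "input_error")
})

test_that("telomeric LINE screen flags families by all three criteria", {
  th <- th_desk() # terminal region 2500
  lens <- len_tbl(s1 = 1e5, s2 = 1e5, s3 = 1e5, s4 = 1e5)
  mk_fam <- function(fam, chroms, pos, n_each) {
    dplyr::bind_rows(lapply(chroms, function(ch) {
      tibble::tibble(chrom = ch, start = pos + (0:(n_each - 1)) * 120,
                     end = pos + (0:(n_each - 1)) * 120 + 80,
                     class = "LINE", family = fam)
    }))
  }
  track <- dplyr::bind_rows(
    mk_fam("telo", c("s1", "s2", "s3", "s4"), 100, 3),   # telomeric, 12 copies
    mk_fam("telo", c("s1", "s2"), 50000, 1),             # a few internal
    mk_fam("bg", c("s1", "s2", "s3", "s4"), 40000, 10)   # background only
  )
  scr <- telomeric_line_screen(track, lens, th, alpha = 0.05,
                               n_telomeres = 8)
  fam <- scr$families
  expect_true(fam$flagged[fam$family == "telo"])
  expect_false(fam$flagged[fam$family == "bg"])
  # with fusion windows covering some telomeric copies the fraction is bounded
  win <- tibble::tibble(chrom = "s1", start = 0, end = 1000)
  scr2 <- telomeric_line_screen(track, lens, th, alpha = 0.05,
                                n_telomeres = 8, fusion_windows = win)
  expect_true(scr2$fraction >= 0 && scr2$fraction <= 1)
  expect_false("telo" %in% scr2$nonflagged_track$family)
  expect_warning(
    telomeric_line_screen(track[0, ], lens, th), regexp = "no LINE")
})

test_that("a family only outside terminal regions is never flagged", {
  th <- th_desk()
  lens <- len_tbl(s1 = 1e5, s2 = 1e5)
  track <- tibble::tibble(chrom = rep(c("s1", "s2"), each = 20),
                          start = rep(seq(30000, 68000, by = 2000), 2))
  track$end <- track$start + 100
  track$class <- "LINE"
  track$family <- "inner"
  scr <- telomeric_line_screen(track, lens, th)
  expect_false(any(scr$families$flagged))
})

test_that("simulator-placed telomeric family is flagged by the screen", {
  cfg <- sim_config(n_chromosomes = 10, element_densities = c(LINE = 0.08),
                    telomere_line_family = "telofam",
                    telomere_line_per_end = 3,
                    singleton_noise_rate = 0, seed = 60)
  g <- simulate_ancestral_genome(cfg)
  tr <- merge_elements(element_track(g))
  scr <- telomeric_line_screen(tr[tr$class == "LINE", ],
                               chromosome_lengths(g), th_desk())
  fam <- scr$families
  expect_true(fam$flagged[fam$family == "telofam"])
  expect_false(any(fam$flagged[fam$family != "telofam"]))
})
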