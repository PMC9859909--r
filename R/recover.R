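# End-to-end comparative pipeline over a simulated species set: every tip in
# turn as reference, breakpoint grouping across the other tips as queries,
# classification, outgroup polarization, and per-branch event counts that
# can be scored against the ground-truth log.

#' Synteny breaks of a focal genome against the ancestral-karyotype genome
#'
#' Aligns the focal genome (as reference) to the ancestral genome, builds
#' blocks and returns the intervals where consecutive blocks switch
#' ancestral chromosome.
#'
#' @param focal,ancestral `karyo_genome`s.
#' @param config The shared [sim_config()].
#' @param thresholds A [thresholds()] bundle.
#' @return Breakpoint tibble on focal coordinates (see
#'   [call_breakpoints()]).
#' @export
outgroup_synteny_breaks <- function(focal, ancestral, config, thresholds) {
  aln <- emit_alignments(focal, ancestral, config)
  blocks <- build_blocks(aln, thresholds)
  call_breakpoints(blocks, chromosome_lengths(focal),
                   query_species = ancestral$species)
}

# Which reference comparison each branch's events are counted from.
# A fusion is interior only to a fused genome, so its canonical reference
# descends from the branch; a fission is visible only from a still-joined
# reference outside the branch's clade. Roles, translated to tip labels.
canonical_refs <- function(tree) {
  list(
    fusion = c(pop1 = "pop1", pop2 = "pop2", pop_stem = "pop1",
               sister = "sister", ingroup_stem = "pop1",
               outgroup = "outgroup"),
    fission = c(pop1 = "pop2", pop2 = "pop1", pop_stem = "sister",
                sister = "pop1", ingroup_stem = "outgroup",
                outgroup = "pop1")
  ) |>
    lapply(function(m) stats::setNames(unname(tree$tips[m]), names(m)))
}

#' Run the full comparative rearrangement inference on a simulation
#'
#' For every tip genome used as reference, emits alignments from the other
#' three tips, builds blocks, calls and groups breakpoints, classifies
#' fission/fusion/shared patterns, computes outgroup-break overlap against
#' the ancestral-karyotype genome, scans junctions for telomeric repeats
#' where the outgroup is uninformative, and polarizes every event to a tree
#' branch. Each event is counted once, from a fixed canonical reference per
#' (branch, event type).
#'
#' @param sim A `karyo_sim` from [simulate_karyotypes()] /
#'   [evolve_karyotype()].
#' @param thresholds A [thresholds()] bundle (use the scale your config was
#'   built for).
#' @param scan_telomeres Scan junction windows of no-overlap events in the
#'   reference sequence for (TTAGG)n / (CCTAA)n arrays.
#' @param min_tandem_copies Tandem copies required to call a telomeric
#'   array.
#' @return A `karyo_recovery`: `counts` (tibble branch / fissions /
#'   fusions), `comparisons` (per-reference `karyo_polarized` objects),
#'   `events` (all polarized events with their reference).
#' @export
recover_events <- function(sim, thresholds, scan_telomeres = TRUE,
                           min_tandem_copies = 5L) {
  tree <- sim$tree
  config <- sim$config
  tips <- sim$tips
  labels <- unname(tree$tips)
  seq_cache <- new.env(parent = emptyenv())
  comparisons <- list()
  all_events <- list()

  for (ref_label in labels) {
    ref <- tips[[ref_label]]
    queries <- setdiff(labels, ref_label)
    ref_len <- chromosome_lengths(ref)
    bps <- dplyr::bind_rows(lapply(queries, function(q) {
      aln <- emit_alignments(ref, tips[[q]], config)
      blocks <- build_blocks(aln, thresholds)
      call_breakpoints(blocks, ref_len, query_species = q)
    }))
    breaks <- outgroup_synteny_breaks(ref, sim$ancestral, config, thresholds)
    if (nrow(bps) == 0L) {
      comparisons[[ref_label]] <- NULL
      next
    }
    groups <- compare_breakpoints(bps, thresholds$overlap_tolerance,
                                  queries = queries)
    events <- classify_fission_fusion(groups, reference = ref_label,
                                      queries = queries)
    events <- overlap_with_outgroup(events, breaks,
                                    thresholds$overlap_tolerance,
                                    scaffold_lengths = ref_len)
    tel <- rep(NA, nrow(events))
    if (scan_telomeres) {
      need <- which(!events$overlap &
                      events$event_type %in% c("fusion", "shared_pair"))
      w <- thresholds$breakpoint_window
      for (i in need) {
        tel[i] <- junction_has_repeats(
          ref, events$ref[i], (events$start[i] + events$end[i]) / 2,
          w, config, seq_cache, min_tandem_copies)
      }
    }
    pol <- polarize_events(events, tree, telomere = tel)
    comparisons[[ref_label]] <- pol
    ev <- pol$events
    all_events[[ref_label]] <- ev
  }

  ev_all <- dplyr::bind_rows(all_events)
  canon <- canonical_refs(tree)
  counts <- dplyr::bind_rows(lapply(tree$branches, function(b) {
    tibble(
      branch = b,
      fusions = if (is.null(comparisons[[canon$fusion[[b]]]])) 0L else
        sum(comparisons[[canon$fusion[[b]]]]$events$final_type == "fusion" &
              comparisons[[canon$fusion[[b]]]]$events$branch == b,
            na.rm = TRUE),
      fissions = if (is.null(comparisons[[canon$fission[[b]]]])) 0L else
        sum(comparisons[[canon$fission[[b]]]]$events$final_type == "fission" &
              comparisons[[canon$fission[[b]]]]$events$branch == b,
            na.rm = TRUE)
    )
  }))
  structure(list(counts = counts, comparisons = comparisons,
                 events = ev_all),
            class = "karyo_recovery")
}

junction_has_repeats <- function(genome, scaffold, mid, window, config,
                                 cache, min_tandem_copies) {
  chrom <- as.integer(sub(".*_chr", "", scaffold))
  key <- paste0(genome$species, ":", chrom)
  if (is.null(cache[[key]])) {
    cache[[key]] <- chromosome_sequence(genome, chrom, config)
  }
  s <- cache[[key]]
  L <- nchar(s)
  lo <- max(1, round(mid - window / 2))
  hi <- min(L, round(mid + window / 2))
  win <- substr(s, lo, hi)
  scan_telomeric_repeats(win, min_tandem_copies = min_tandem_copies)$present
}

#' @export
print.karyo_recovery <- function(x, ...) {
  cat("<karyo_recovery> per-branch event counts:\n")
  print(x$counts)
  invisible(x)
}

#' Compare recovered per-branch counts with a ground-truth log
#'
#' @param recovery A `karyo_recovery` from [recover_events()].
#' @param log Ground-truth log of the same simulation.
#' @return Tibble: `branch`, `type`, `truth`, `called`, `exact`.
#' @export
score_recovery <- function(recovery, log) {
  truth <- summarize_log(log) |>
    dplyr::filter(type %in% c("fission", "fusion"))
  called <- recovery$counts |>
    tidyr::pivot_longer(c(fissions, fusions), names_to = "type",
                        values_to = "called") |>
    dplyr::mutate(type = sub("s$", "", type))
  res <- dplyr::full_join(truth, called, by = c("branch", "type")) |>
    dplyr::mutate(
      truth = dplyr::coalesce(n, 0L),
      called = dplyr::coalesce(called, 0L)
    ) |>
    dplyr::select(branch, type, truth, called) |>
    dplyr::mutate(exact = truth == called)
  res
}
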