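# Polarization of fission/fusion calls against an ancestral-karyotype
# outgroup, a randomization test for breakpoint/synteny-break overlap, and
# telomeric-repeat scanning.

#' Flag events that overlap outgroup synteny breaks
#'
#' A focal breakpoint overlapping a synteny break against the
#' ancestral-karyotype genome means the ancestral state at that locus is
#' split, so the joined (fused) arrangement is the derived one.
#'
#' @param events Tibble with `ref`, `start`, `end` (focal-genome
#'   coordinates).
#' @param outgroup_breaks Tibble with `ref`, `start`, `end`: intervals where
#'   consecutive alignment blocks against the ancestral-karyotype genome
#'   switch ancestral chromosome (e.g. [call_breakpoints()] of focal
#'   vs. outgroup blocks).
#' @param tolerance Symmetric padding, bp; padded intervals that touch count
#'   as overlapping (zero-length breakpoints are points).
#' @param scaffold_lengths Optional length tibble; when given, events on
#'   unknown scaffolds raise an input error (coordinate-system check).
#' @return `events` with a logical `overlap` column; attributes
#'   `n_overlap` and `n_total`.
#' @export
overlap_with_outgroup <- function(events, outgroup_breaks, tolerance,
                                  scaffold_lengths = NULL) {
  assert_cols(events, c("ref", "start", "end"), "events")
  if (!is.null(scaffold_lengths) &&
      !all(events$ref %in% scaffold_lengths$chrom)) {
    ks_abort("event scaffold not present in scaffold_lengths (coordinate mismatch)",
             "input_error")
  }
  set <- tibble(chrom = outgroup_breaks$ref,
                start = outgroup_breaks$start, end = outgroup_breaks$end)
  events$overlap <- iv_overlaps_any(events$ref, events$start, events$end,
                                    set, tol = tolerance)
  attr(events, "n_overlap") <- sum(events$overlap)
  attr(events, "n_total") <- nrow(events)
  events
}

#' Randomization test for breakpoint/synteny-break overlap
#'
#' Places the observed breakpoint intervals (sizes preserved) uniformly at
#' random across the genome, fully within scaffolds, independently of one
#' another, and counts how often the randomized overlap count reaches the
#' observed one. The empirical p-value uses the add-one correction
#' `p = (#\{count >= observed\} + 1) / (n_iter + 1)`, so p is never 0.
#'
#' @param breakpoints Tibble with `ref`, `start`, `end` (the observed
#'   intervals whose sizes are reused).
#' @param lengths Scaffold length tibble (`chrom`, `length`).
#' @param outgroup_breaks Synteny-break tibble (`ref`, `start`, `end`).
#' @param n_iter Iterations (>= 1).
#' @param seed Integer seed.
#' @param tolerance Padding used in the overlap rule (same rule as
#'   [overlap_with_outgroup()]).
#' @param observed Observed overlap count; computed from `breakpoints` when
#'   `NULL`.
#' @return A `karyo_randtest`: `p`, `observed`, `n_iter`, `null_counts`.
#' @export
randomization_test <- function(breakpoints, lengths, outgroup_breaks,
                               n_iter = 10000, seed = 1, tolerance = 0,
                               observed = NULL) {
  assert_cols(breakpoints, c("ref", "start", "end"), "breakpoints")
  assert_cols(lengths, c("chrom", "length"), "lengths")
  if (nrow(breakpoints) == 0L) {
    ks_abort("randomization test needs at least one breakpoint",
             "input_error")
  }
  if (n_iter < 1) ks_abort("n_iter must be >= 1", "input_error")
  if (is.null(observed)) {
    ov <- overlap_with_outgroup(breakpoints, outgroup_breaks, tolerance)
    observed <- sum(ov$overlap)
  }
  widths <- round(breakpoints$end - breakpoints$start)
  L <- round(lengths$length)
  set <- tibble(chrom = outgroup_breaks$ref,
                start = outgroup_breaks$start, end = outgroup_breaks$end)
  withr::with_seed(seed, {
    counts <- matrix(FALSE, nrow = n_iter, ncol = length(widths))
    for (j in seq_along(widths)) {
      w <- widths[j]
      valid <- which(L >= w)
      if (length(valid) == 0L) {
        ks_abort("a breakpoint is longer than every scaffold",
                 "placement_error")
      }
      slots <- L[valid] - w + 1
      ci <- valid[sample.int(length(valid), n_iter, replace = TRUE,
                             prob = slots)]
      starts <- floor(stats::runif(n_iter) * (L[ci] - w + 1))
      counts[, j] <- iv_overlaps_any(lengths$chrom[ci], starts, starts + w,
                                     set, tol = tolerance)
    }
    null_counts <- rowSums(counts)
    p <- (sum(null_counts >= observed) + 1) / (n_iter + 1)
    structure(list(p = p, observed = observed, n_iter = n_iter,
                   null_counts = null_counts),
              class = "karyo_randtest")
  })
}

#' @export
print.karyo_randtest <- function(x, ...) {
  cat(sprintf(
    "<karyo_randtest> observed overlap = %d; empirical p = %.3g (%d iterations)\n",
    x$observed, x$p, x$n_iter))
  invisible(x)
}

#' Scan a sequence window for tandem telomeric repeats
#'
#' Reports whether the insect telomere motif occurs as a tandem array of at
#' least `min_tandem_copies` consecutive copies of TTAGG or of its reverse
#' complement CCTAA. An N breaks a candidate run.
#'
#' @param sequence A character string (or `DNAString`) of A/C/G/T/N.
#' @param motifs Motifs scanned for tandem runs.
#' @param min_tandem_copies Minimum consecutive copies to call presence.
#' @return One-row tibble: `present`, `copies` (longest tandem run over all
#'   motifs), `motif` (motif of that run, `NA` when no copy found).
#' @examples
#' scan_telomeric_repeats(strrep("TTAGG", 10))
#' @export
scan_telomeric_repeats <- function(sequence,
                                   motifs = c("TTAGG", "CCTAA"),
                                   min_tandem_copies = 5L) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s)) {
    ks_abort("sequence contains characters other than A/C/G/T/N",
             "sequence_error")
  }
  best <- 0L
  best_motif <- NA_character_
  for (m in motifs) {
    hits <- gregexpr(paste0("(?:", m, ")+"), s, perl = TRUE)[[1]]
    if (hits[1] != -1L) {
      copies <- max(attr(hits, "match.length")) %/% nchar(m)
      if (copies > best) {
        best <- copies
        best_motif <- m
      }
    }
  }
  tibble(present = best >= min_tandem_copies, copies = best,
         motif = best_motif)
}

#' Polarize classified events with outgroup and telomere evidence
#'
#' Applies a fixed, auditable rule order to each classified event:
#' \enumerate{
#'   \item fusion call + outgroup overlap: confirmed fusion in the joined
#'     lineage(s).
#'   \item no overlap + telomeric repeats at the junction: fusion restoring
#'     the ancestral (joined) state.
#'   \item fusion call + no overlap + no repeats: ambiguous (recurrent
#'     fission or differentially sorted ancestral polymorphism).
#'   \item shared-pair or fission call + overlap: fusion in the joined
#'     lineage(s).
#'   \item shared-pair or fission call + no overlap + no repeats: fission in
#'     the breaking lineage(s).
#' }
#' The joined set is the reference plus the queries without the breakpoint;
#' the derived state is read from the outgroup: overlap with an
#' ancestral-karyotype synteny break means the ancestor is split there, so
#' the joined arrangement is derived. A set of lineages that is not a clade
#' of the tree is reported `ambiguous`, and an event missing required
#' evidence is reported `unresolved` — never guessed.
#'
#' @param events Classified calls from [classify_fission_fusion()]
#'   (possibly several references bound together). Must carry `reference`,
#'   `event_type`, `shared_by`.
#' @param tree The [karyo_tree()] naming tips and clades.
#' @param overlap Logical vector (length `nrow(events)`) of outgroup-break
#'   overlap flags, or `NULL` to use an `overlap` column of `events`.
#' @param telomere Logical vector: telomeric repeats present at the junction
#'   in the joined lineage(s); `NA` where not scanned. `NULL` means no scan
#'   anywhere.
#' @return A `karyo_polarized`: `events` (with `final_type`, `branch`,
#'   `rule`), `summary` (per-branch fusion/fission counts),
#'   `n_overlap` / `n_total`, and `fusion_fraction` — the percentage of
#'   considered breakpoints polarized as fusions within the clade
#'   (100 x clade fusions / breakpoints considered).
#' @export
polarize_events <- function(events, tree = karyo_tree(),
                            overlap = NULL, telomere = NULL) {
  assert_cols(events, c("reference", "event_type", "shared_by"), "events")
  n <- nrow(events)
  ov <- overlap %||% events$overlap %||% rep(NA, n)
  tel <- telomere %||%
    (if ("telomere_repeats" %in% names(events)) events$telomere_repeats
     else rep(NA, n))
  if (length(ov) != n || length(tel) != n) {
    ks_abort("overlap/telomere evidence must match the number of events",
             "input_error")
  }
  tips <- unname(tree$tips)
  final_type <- character(n); branch <- character(n); rule <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    breakers <- events$shared_by[[i]]
    joined <- union(events$reference[i],
                    setdiff(setdiff(tips, events$reference[i]), breakers))
    et <- events$event_type[i]
    if (is.na(ov[i])) {
      final_type[i] <- "unresolved"; branch[i] <- NA_character_
    } else if (isTRUE(ov[i])) {
      b <- branch_for_clade(tree, joined)
      rule[i] <- if (et == "fusion") 1L else 4L
      if (is.na(b)) {
        final_type[i] <- "ambiguous"; branch[i] <- NA_character_
      } else {
        final_type[i] <- "fusion"; branch[i] <- b
      }
    } else if (isTRUE(tel[i])) {
      b <- branch_for_clade(tree, joined)
      rule[i] <- 2L
      final_type[i] <- "ancestral_fusion"
      branch[i] <- if (is.na(b)) NA_character_ else b
    } else if (et == "fission") {
      # unique breakpoint, ancestor joined: the split is derived
      rule[i] <- 5L
      final_type[i] <- "fission"
      branch[i] <- branch_for_clade(tree, breakers)
      if (is.na(branch[i])) final_type[i] <- "ambiguous"
    } else if (is.na(tel[i])) {
      # fusion/shared_pair without overlap needs the telomere scan
      final_type[i] <- "unresolved"; branch[i] <- NA_character_
    } else {
      # no repeats: a clade of breakers is one fission on that branch;
      # a non-clade set would need recurrent fissions or differential
      # sorting of an ancestral polymorphism, which stays ambiguous
      b <- branch_for_clade(tree, breakers)
      if (!is.na(b)) {
        rule[i] <- 5L
        final_type[i] <- "fission"; branch[i] <- b
      } else {
        rule[i] <- 3L
        final_type[i] <- "ambiguous"; branch[i] <- NA_character_
      }
    }
  }
  ev <- events
  ev$overlap <- ov
  ev$telomere_repeats <- tel
  ev$final_type <- final_type
  ev$branch <- branch
  ev$rule <- rule
  considered <- sum(!is.na(ov))
  clade_fusions <- sum(final_type == "fusion" & rule %in% c(1L, 4L),
                       na.rm = TRUE)
  summary <- ev |>
    dplyr::filter(final_type %in% c("fusion", "fission", "ancestral_fusion"),
                  !is.na(branch)) |>
    dplyr::count(branch, final_type, name = "n") |>
    tidyr::pivot_wider(names_from = final_type, values_from = n,
                       values_fill = 0L)
  for (col in c("fusion", "fission", "ancestral_fusion")) {
    if (!col %in% names(summary)) summary[[col]] <- 0L
  }
  structure(list(
    events = ev,
    summary = summary,
    n_overlap = sum(ov, na.rm = TRUE),
    n_total = considered,
    fusion_fraction = if (considered > 0) 100 * clade_fusions / considered
                      else NA_real_
  ), class = "karyo_polarized")
}

#' @export
print.karyo_polarized <- function(x, ...) {
  cat(sprintf(
    "<karyo_polarized> %d events considered; %d overlap outgroup breaks; clade fusion fraction %.1f%%\n",
    x$n_total, x$n_overlap, x$fusion_fraction))
  print(x$summary)
  invisible(x)
}
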