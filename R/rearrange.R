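# Cross-species comparison of breakpoints on a shared reference:
# grouping, fission/fusion classification, translocation patterns, and
# ancestral chromosome-end accounting.

#' Group breakpoints from several query species on one reference
#'
#' Breakpoints are grouped by transitive closure of pairwise interval
#' overlap after symmetric padding by `tolerance` (single-linkage, matching
#' what interval intersection across more than two species does). Each group
#' records the exact subset of query species contributing a breakpoint.
#'
#' @param breakpoints Breakpoint tibble (from [call_breakpoints()], rows
#'   from all query species bound together) with a `query_species` column.
#' @param tolerance Symmetric padding in bp; zero-length breakpoints are
#'   treated as points, and padded intervals that touch are grouped.
#' @param queries Full set of query species in the comparison (>= 2);
#'   defaults to the species observed in `breakpoints`.
#' @return Tibble, one row per group: `group_id`, `ref`, `start`, `end`
#'   (unpadded extremes), `shared_by` (list column of species), `n_species`,
#'   `n_breakpoints`, plus `left_q_edge`/`right_q_edge`/`left_query`/
#'   `right_query` of the representative (first) member.
#' @export
compare_breakpoints <- function(breakpoints, tolerance, queries = NULL) {
  assert_cols(breakpoints, c("ref", "start", "end", "query_species"),
              "breakpoints")
  qs <- queries %||% unique(breakpoints$query_species)
  if (length(qs) < 2L) {
    ks_abort("compare_breakpoints() needs breakpoints from at least two query species",
             "insufficient_queries_error")
  }
  b <- breakpoints
  for (col in c("left_query", "right_query")) {
    if (!col %in% names(b)) b[[col]] <- NA_character_
  }
  for (col in c("left_q_edge", "right_q_edge")) {
    if (!col %in% names(b)) b[[col]] <- NA_real_
  }
  b <- b[order(b$ref, b$start, b$end), , drop = FALSE]
  b$group_id <- NA_integer_
  gid <- 0L
  out <- list()
  for (d in split(b, b$ref)) {
    run_end <- -Inf
    ids <- integer(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (d$start[i] - tolerance > run_end) gid <- gid + 1L
      ids[i] <- gid
      run_end <- max(run_end, d$end[i] + tolerance)
    }
    d$group_id <- ids
    out[[length(out) + 1L]] <- d
  }
  b <- dplyr::bind_rows(out)
  b |>
    dplyr::group_by(group_id, ref) |>
    dplyr::summarise(
      start = min(start), end = max(end),
      shared_by = list(sort(unique(query_species))),
      n_species = length(unique(query_species)),
      n_breakpoints = dplyr::n(),
      left_query = left_query[1], right_query = right_query[1],
      left_q_edge = left_q_edge[1], right_q_edge = right_q_edge[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(group_id)
}

#' Classify breakpoint groups as fissions, fusions or shared pairs
#'
#' A breakpoint unique to one query species is a fission in that query; a
#' breakpoint shared by all query species is a fusion in the reference; a
#' breakpoint shared by a proper subset is emitted as `shared_pair` and left
#' for polarization (candidate incomplete lineage sorting, breakpoint reuse,
#' or an event on an internal branch) — it is never silently assigned.
#'
#' @param groups Output of [compare_breakpoints()].
#' @param reference Reference species label.
#' @param queries Character vector of all query species compared.
#' @return Tibble of event calls: the group columns plus `event_type`
#'   (`fission` / `fusion` / `shared_pair`), `lineage` (query for fissions,
#'   reference for fusions, `NA` for shared pairs), `reference`, and the
#'   evidence flag columns `unique_to_one_query` / `shared_by_all_queries` /
#'   `shared_by_subset`.
#' @export
classify_fission_fusion <- function(groups, reference, queries) {
  if (nrow(groups) == 0L) {
    return(dplyr::mutate(groups, event_type = character(0),
                         lineage = character(0),
                         reference = character(0),
                         unique_to_one_query = logical(0),
                         shared_by_all_queries = logical(0),
                         shared_by_subset = logical(0)))
  }
  is_all <- vapply(groups$shared_by, function(s) setequal(s, queries),
                   logical(1))
  n <- groups$n_species
  groups |>
    dplyr::mutate(
      event_type = dplyr::case_when(
        is_all ~ "fusion",
        n == 1L ~ "fission",
        TRUE ~ "shared_pair"
      ),
      lineage = dplyr::case_when(
        is_all ~ reference,
        n == 1L ~ vapply(shared_by, `[[`, character(1), 1L),
        TRUE ~ NA_character_
      ),
      reference = reference,
      unique_to_one_query = n == 1L & !is_all,
      shared_by_all_queries = is_all,
      shared_by_subset = !is_all & n > 1L
    )
}

#' Detect translocation patterns between two genomes
#'
#' Reciprocal: two reference scaffolds each contain blocks from the same two
#' query scaffolds (the two chromosomes carry the same combination of parts
#' of two chromosomes of the other species). Non-reciprocal: one reference
#' scaffold's ordered block list contains the flanking pattern
#' query-i, query-j, query-i (one foreign block inside another chromosome's
#' span). Fission/fusion histories can in principle mimic the reciprocal
#' pattern; calls are labelled, not proven.
#'
#' @param blocks Block tibble from [build_blocks()] for one species pair.
#' @return Tibble of event calls: `event_type`
#'   (`reciprocal_translocation` / `nonreciprocal_translocation`),
#'   `ref_scaffolds`, `query_scaffolds` (comma-separated), `ref`, `start`,
#'   `end` (span of the supporting blocks on the first scaffold).
#' @export
detect_translocations <- function(blocks) {
  empty <- tibble(event_type = character(), ref_scaffolds = character(),
                  query_scaffolds = character(), ref = character(),
                  start = double(), end = double())
  if (nrow(blocks) == 0L) return(empty)
  b <- blocks[order(blocks$ref, blocks$ref_start), , drop = FALSE]
  out <- list()
  # reciprocal: unordered query pair present on >= 2 reference scaffolds
  pair_tbl <- b |>
    dplyr::distinct(ref, query) |>
    dplyr::group_by(ref) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(pairs = list({
      q <- sort(unique(query))
      if (length(q) >= 2) apply(utils::combn(q, 2), 2,
                                paste, collapse = ",")
      else character(0)
    }), .groups = "drop") |>
    tidyr::unnest(pairs)
  if (nrow(pair_tbl) > 0L) {
    dup <- pair_tbl |>
      dplyr::group_by(pairs) |>
      dplyr::filter(dplyr::n() >= 2L) |>
      dplyr::summarise(refs = list(sort(unique(ref))), .groups = "drop")
    for (i in seq_len(nrow(dup))) {
      refs <- dup$refs[[i]]
      span <- b[b$ref == refs[1], , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        event_type = "reciprocal_translocation",
        ref_scaffolds = paste(refs, collapse = ","),
        query_scaffolds = dup$pairs[i],
        ref = refs[1], start = min(span$ref_start), end = max(span$ref_end)
      )
    }
  }
  # non-reciprocal: flanking pattern q_i, q_j, q_i along one scaffold
  for (d in split(b, b$ref)) {
    q <- d$query
    n <- length(q)
    if (n >= 3L) {
      hit <- which(q[-c(n - 1L, n)] == q[-c(1L, 2L)] &
                     q[-c(n - 1L, n)] != q[-c(1L, n)])
      for (k in hit) {
        out[[length(out) + 1L]] <- tibble(
          event_type = "nonreciprocal_translocation",
          ref_scaffolds = d$ref[1],
          query_scaffolds = paste(unique(c(q[k], q[k + 1L])), collapse = ","),
          ref = d$ref[1], start = d$ref_start[k + 1L], end = d$ref_end[k + 1L]
        )
      }
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Count retained ancestral chromosome ends
#'
#' An ancestral (reference) chromosome end is retained in the focal species
#' when a synteny block overlapping that chromosome's terminal `end_window`
#' has its corresponding query edge within `end_window` of a focal scaffold
#' end. A pair is retained when both ends of one ancestral chromosome are
#' retained on the same focal scaffold.
#'
#' @param blocks Blocks of focal species (query) against the
#'   ancestral-karyotype genome (reference), from [build_blocks()].
#' @param ref_lengths,query_lengths Length tibbles (`chrom`, `length`).
#' @param end_window Terminal window, bp (commonly the telomeric screen
#'   window).
#' @param species Focal species label.
#' @return One-row tibble: `species`, `retained`, `total`, `pairs`.
#' @export
count_ancestral_ends <- function(blocks, ref_lengths, query_lengths,
                                 end_window, species = NA_character_) {
  assert_cols(ref_lengths, c("chrom", "length"), "ref_lengths")
  assert_cols(query_lengths, c("chrom", "length"), "query_lengths")
  total <- 2L * nrow(ref_lengths)
  if (nrow(blocks) == 0L) {
    return(tibble(species = species, retained = 0L, total = total,
                  pairs = 0L))
  }
  qlen <- stats::setNames(query_lengths$length, query_lengths$chrom)
  retained <- list()
  for (i in seq_len(nrow(ref_lengths))) {
    ch <- ref_lengths$chrom[i]; L <- ref_lengths$length[i]
    d <- blocks[blocks$ref == ch, , drop = FALSE]
    if (nrow(d) == 0L) next
    for (side in c("left", "right")) {
      cand <- if (side == "left") {
        d[d$ref_start < end_window, , drop = FALSE]
      } else {
        d[d$ref_end > L - end_window, , drop = FALSE]
      }
      if (nrow(cand) == 0L) next
      cand <- if (side == "left") {
        cand[which.min(cand$ref_start), ]
      } else {
        cand[which.max(cand$ref_end), ]
      }
      qpos <- if (side == "left") cand$q_edge_left else cand$q_edge_right
      Lq <- qlen[[cand$query]]
      if (min(qpos, Lq - qpos) <= end_window) {
        retained[[length(retained) + 1L]] <- tibble(
          anc_chrom = ch, side = side, scaffold = cand$query)
      }
    }
  }
  ret <- dplyr::bind_rows(retained)
  n_ret <- nrow(ret)
  pairs <- 0L
  if (n_ret > 0L) {
    pairs <- ret |>
      dplyr::group_by(anc_chrom, scaffold) |>
      dplyr::summarise(both = dplyr::n() == 2L, .groups = "drop") |>
      dplyr::pull(both) |>
      sum()
  }
  tibble(species = species, retained = n_ret, total = total,
         pairs = as.integer(pairs))
}
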