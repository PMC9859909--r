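# Synteny-block construction and breakpoint calling on a reference genome.

#' Build filtered synteny blocks from alignment records
#'
#' Discards alignments at or below `min_identity`, sorts the remainder along
#' each reference scaffold, removes "singleton" interruptions — maximal runs
#' of consecutive alignments to one query scaffold whose summed reference
#' span is below `min_block` and whose two flanking runs share a different,
#' single query scaffold — and merges each maximal surviving run sharing a
#' query scaffold into one block. Blocks whose summed aligned reference bp
#' is not strictly greater than `min_block` are dropped (for contiguous
#' alignment tilings this equals the block span). Gap tolerance within a run
#' is unlimited: consecutive alignments to the same query merge no matter
#' the gap, provided no surviving block intervenes.
#'
#' @param alignments Alignment tibble (one reference genome, one query
#'   genome; see [read_alignments()]).
#' @param thresholds A [thresholds()] bundle.
#' @return Tibble of blocks: `ref`, `ref_start`, `ref_end`, `query`,
#'   `query_start`, `query_end`, `strand` (majority aligned bp; ties "+"),
#'   `n_aln`, `aligned_bp`, and `q_edge_left` / `q_edge_right` — the query
#'   coordinate aligned at the block's left / right reference edge (used for
#'   query-side breakpoint windows).
#' @examples
#' th <- thresholds(scale_factor = 1 / 100)
#' aln <- tibble::tibble(
#'   ref = "r1", ref_start = 0, ref_end = 150000, query = "q1",
#'   query_start = 0, query_end = 150000, identity = 95, strand = "+"
#' )
#' build_blocks(aln, th)
#' @export
build_blocks <- function(alignments, thresholds) {
  assert_cols(alignments, aln_cols, "alignments")
  a <- alignments[alignments$identity > thresholds$min_identity, , drop = FALSE]
  if (nrow(a) == 0L) return(empty_blocks())
  a <- a[order(a$ref, a$ref_start, a$ref_end), , drop = FALSE]
  out <- lapply(split(a, a$ref), blocks_one_scaffold,
                min_block = thresholds$min_block)
  res <- dplyr::bind_rows(out)
  res[order(res$ref, res$ref_start), , drop = FALSE]
}

empty_blocks <- function() {
  tibble(ref = character(), ref_start = double(), ref_end = double(),
         query = character(), query_start = double(), query_end = double(),
         strand = character(), n_aln = integer(), aligned_bp = double(),
         q_edge_left = double(), q_edge_right = double())
}

blocks_one_scaffold <- function(d, min_block) {
  repeat {
    r <- rle(d$query)
    if (length(r$lengths) < 3L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    span <- vapply(seq_along(starts), function(i) {
      sum(d$ref_end[starts[i]:ends[i]] - d$ref_start[starts[i]:ends[i]])
    }, numeric(1))
    iseq <- seq_along(starts)
    singleton <- iseq > 1L & iseq < length(starts) &
      span < min_block &
      r$values[pmax(iseq - 1L, 1L)] == r$values[pmin(iseq + 1L, length(iseq))] &
      r$values[pmax(iseq - 1L, 1L)] != r$values
    if (!any(singleton)) break
    drop_rows <- unlist(lapply(which(singleton),
                               function(i) starts[i]:ends[i]))
    d <- d[-drop_rows, , drop = FALSE]
  }
  r <- rle(d$query)
  n_runs <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  grp <- rep(seq_len(n_runs), r$lengths)
  w <- d$ref_end - d$ref_start
  plus_bp <- unname(rowsum(w * (d$strand == "+"), grp)[, 1])
  tot_bp <- unname(rowsum(w, grp)[, 1])
  last_i <- integer(n_runs); ref_end_blk <- numeric(n_runs)
  q_min <- numeric(n_runs); q_max <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    sl <- starts[i]:ends[i]
    li <- sl[which.max(d$ref_end[sl])]
    last_i[i] <- li
    ref_end_blk[i] <- d$ref_end[li]
    q_min[i] <- min(d$query_start[sl])
    q_max[i] <- max(d$query_end[sl])
  }
  res <- tibble::new_tibble(list(
    ref = rep(d$ref[1], n_runs),
    ref_start = d$ref_start[starts],
    ref_end = ref_end_blk,
    query = r$values,
    query_start = q_min,
    query_end = q_max,
    strand = ifelse(tot_bp - plus_bp > plus_bp, "-", "+"),
    n_aln = as.integer(r$lengths),
    aligned_bp = tot_bp,
    q_edge_left = ifelse(d$strand[starts] == "+",
                         d$query_start[starts], d$query_end[starts]),
    q_edge_right = ifelse(d$strand[last_i] == "+",
                          d$query_end[last_i], d$query_start[last_i])
  ), nrow = n_runs)
  # size filter on summed aligned reference bp (consistent with the
  # singleton rule); identical to the end-to-start span for contiguous
  # tilings, but robust to sparse spurious runs straddling a wide span
  res <- res[res$aligned_bp > min_block, , drop = FALSE]
  # dropped interruptions can leave two adjacent blocks on one query;
  # merge them so filtering is idempotent
  if (nrow(res) > 1L) {
    r2 <- rle(res$query)
    if (length(r2$lengths) < nrow(res)) {
      g2 <- rep(seq_along(r2$lengths), r2$lengths)
      first <- !duplicated(g2)
      last <- !duplicated(g2, fromLast = TRUE)
      plus_w <- unname(rowsum(res$aligned_bp * (res$strand == "+"), g2)[, 1])
      tot_w <- unname(rowsum(res$aligned_bp, g2)[, 1])
      res <- tibble::new_tibble(list(
        ref = res$ref[first],
        ref_start = res$ref_start[first],
        ref_end = res$ref_end[last],
        query = r2$values,
        query_start = unname(tapply(res$query_start, g2, min)),
        query_end = unname(tapply(res$query_end, g2, max)),
        strand = ifelse(tot_w - plus_w > plus_w, "-", "+"),
        n_aln = unname(rowsum(res$n_aln, g2)[, 1]),
        aligned_bp = tot_w,
        q_edge_left = res$q_edge_left[first],
        q_edge_right = res$q_edge_right[last]
      ), nrow = length(r2$lengths))
    }
  }
  res
}

#' Call breakpoints between adjacent synteny blocks
#'
#' One breakpoint per adjacent block pair on the same reference scaffold
#' whose query scaffolds differ. The breakpoint interval is the gap between
#' the two blocks (zero-length when they abut).
#'
#' @param blocks Block tibble from [build_blocks()].
#' @param ref_lengths Reference scaffold length tibble (`chrom`, `length`);
#'   required to compute the distance to the nearer scaffold end.
#' @param query_species Optional provenance label stored with each
#'   breakpoint.
#' @return Tibble: `ref`, `start`, `end`, `left_query`, `right_query`,
#'   `left_q_edge`, `right_q_edge`, `terminal_distance`, `query_species`.
#' @export
call_breakpoints <- function(blocks, ref_lengths,
                             query_species = NA_character_) {
  assert_cols(blocks, c("ref", "ref_start", "ref_end", "query"), "blocks")
  assert_cols(ref_lengths, c("chrom", "length"), "ref_lengths")
  if (!all(blocks$ref %in% ref_lengths$chrom)) {
    ks_abort("blocks reference scaffolds missing from ref_lengths",
             "input_error")
  }
  if (nrow(blocks) == 0L) return(empty_breakpoints())
  b <- blocks[order(blocks$ref, blocks$ref_start), , drop = FALSE]
  Lmap <- stats::setNames(ref_lengths$length, ref_lengths$chrom)
  n <- nrow(b)
  if (n < 2L) return(empty_breakpoints())
  i <- which(b$ref[-n] == b$ref[-1] & b$query[-n] != b$query[-1])
  if (length(i) == 0L) return(empty_breakpoints())
  s <- pmin(b$ref_end[i], b$ref_start[i + 1L])
  e <- pmax(b$ref_end[i], b$ref_start[i + 1L])
  L <- unname(Lmap[b$ref[i]])
  tibble::new_tibble(list(
    ref = b$ref[i], start = s, end = e,
    left_query = b$query[i], right_query = b$query[i + 1L],
    left_q_edge = b$q_edge_right[i], right_q_edge = b$q_edge_left[i + 1L],
    terminal_distance = pmin(s, L - e),
    query_species = rep(query_species, length(i))
  ), nrow = length(i))
}

empty_breakpoints <- function() {
  tibble(ref = character(), start = double(), end = double(),
         left_query = character(), right_query = character(),
         left_q_edge = double(), right_q_edge = double(),
         terminal_distance = double(), query_species = character())
}
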