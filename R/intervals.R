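# Interval algebra on 0-based half-open genomic intervals.
#
# All coordinates in the package are 0-based half-open internally; file
# dialects (nucmer coords: 1-based inclusive; BED: 0-based half-open) are
# converted at the I/O boundary only.

# Merge possibly overlapping intervals within each chromosome.
# x: data frame with chrom, start, end. Returns sorted, disjoint intervals.
iv_merge <- function(x) {
  if (nrow(x) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- lapply(split(x, x$chrom), function(d) {
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]
    res_s <- double(); res_e <- double()
    if (length(s) > 1L) {
      for (i in 2:length(s)) {
        if (s[i] <= keep_e) {
          keep_e <- max(keep_e, e[i])
        } else {
          res_s <- c(res_s, keep_s); res_e <- c(res_e, keep_e)
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
    }
    res_s <- c(res_s, keep_s); res_e <- c(res_e, keep_e)
    tibble(chrom = d$chrom[1], start = res_s, end = res_e)
  })
  dplyr::bind_rows(out)
}

# Coverage index for fast covered-bp queries against a merged track.
# Returns, per chromosome, sorted interval starts/ends and cumulative covered
# bp up to the start of each interval.
iv_index <- function(track) {
  track <- iv_merge(track)
  lapply(split(track, track$chrom), function(d) {
    w <- d$end - d$start
    list(start = d$start, end = d$end, cum = cumsum(c(0, w)))
  })
}

# Covered bp of [start, end) windows against an iv_index. Vectorized.
iv_covered <- function(index, chrom, start, end) {
  out <- numeric(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    idx <- index[[cn]]
    if (is.null(idx)) next
    s <- start[sel]; e <- end[sel]
    # covered bp in [0, x): full intervals before + partial inside current
    cov_to <- function(x) {
      i <- findInterval(x, idx$start)          # intervals with start <= x
      full <- idx$cum[pmax(i, 1L)] * (i > 0L)  # covered before interval i
      inside <- ifelse(i > 0L, pmin(x, idx$end[pmax(i, 1L)]) - idx$start[pmax(i, 1L)], 0)
      full + pmax(inside, 0)
    }
    out[sel] <- cov_to(e) - cov_to(s)
  }
  out
}

# Do closed intervals [s1,e1] and any of [s2,e2] (same chrom) intersect after
# symmetric padding by tol? Vectorized over the first set.
iv_overlaps_any <- function(x_chrom, x_start, x_end, set, tol = 0) {
  if (nrow(set) == 0L) return(rep(FALSE, length(x_chrom)))
  padded <- iv_merge_closed(tibble(
    chrom = set$chrom, start = set$start - tol, end = set$end + tol
  ))
  out <- logical(length(x_chrom))
  for (cn in unique(x_chrom)) {
    sel <- x_chrom == cn
    d <- padded[padded$chrom == cn, , drop = FALSE]
    if (nrow(d) == 0L) next
    # merged closed intervals, sorted: candidate = last with start <= x_end
    i <- findInterval(x_end[sel] + tol, d$start)
    hit <- i > 0L & d$end[pmax(i, 1L)] >= x_start[sel] - tol
    out[sel] <- hit
  }
  out
}

# Merge treating intervals as closed (touching intervals join); used for
# padded overlap logic where zero-length breakpoints are points.
iv_merge_closed <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- lapply(split(x, x$chrom), function(d) {
    s <- d$start; e <- d$end
    res_s <- s[1]; res_e <- e[1]
    if (length(s) > 1L) {
      for (i in 2:length(s)) {
        k <- length(res_s)
        if (s[i] <= res_e[k]) {
          res_e[k] <- max(res_e[k], e[i])
        } else {
          res_s <- c(res_s, s[i]); res_e <- c(res_e, e[i])
        }
      }
    }
    tibble(chrom = d$chrom[1], start = res_s, end = res_e)
  })
  dplyr::bind_rows(out)
}
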