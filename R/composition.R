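# Breakpoint-region composition: element-track preparation, window
# standardization, resampling enrichment tests, and the telomere-associated
# LINE screen.

#' Merge element annotations into per-class tracks
#'
#' Overlapping intervals of the same class are unioned. LINE family labels
#' are preserved: where intervals of different families overlap, they are
#' split at the boundaries and each sub-interval keeps the family of the
#' first interval covering it (by coordinate order).
#'
#' @param elements Tibble: `chrom`, `start`, `end`, `class`, optionally
#'   `family`.
#' @return Sorted track tibble with non-overlapping intervals per class.
#' @export
merge_elements <- function(elements) {
  assert_cols(elements, c("chrom", "start", "end", "class"), "elements")
  if (nrow(elements) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  class = character(), family = character()))
  }
  if (any(elements$end <= elements$start)) {
    ks_abort("element interval with end <= start", "input_error")
  }
  if (!"family" %in% names(elements)) elements$family <- NA_character_
  out <- lapply(split(elements, elements$class), function(d) {
    cls <- d$class[1]
    if (all(is.na(d$family))) {
      m <- iv_merge(d[, c("chrom", "start", "end")])
      m$class <- cls
      m$family <- NA_character_
      return(m)
    }
    dplyr::bind_rows(lapply(split(d, d$chrom), function(dc) {
      dc <- dc[order(dc$start, dc$end), , drop = FALSE]
      if (all(dc$start[-1] >= dc$end[-nrow(dc)]) || nrow(dc) == 1L) {
        return(tibble(chrom = dc$chrom, start = dc$start, end = dc$end,
                      class = cls, family = dc$family))
      }
      bounds <- sort(unique(c(dc$start, dc$end)))
      a_s <- utils::head(bounds, -1L); a_e <- bounds[-1L]
      fam <- rep(NA_character_, length(a_s))
      for (i in seq_along(a_s)) {
        cover <- which(dc$start <= a_s[i] & dc$end >= a_e[i])
        if (length(cover) > 0L) fam[i] <- dc$family[cover[1]]
      }
      keep <- !is.na(fam)
      a_s <- a_s[keep]; a_e <- a_e[keep]; fam <- fam[keep]
      # merge contiguous atoms of the same family
      if (length(a_s) > 1L) {
        brk <- c(TRUE, a_s[-1] != a_e[-length(a_e)] |
                   fam[-1] != fam[-length(fam)])
        grp <- cumsum(brk)
        a_s <- tapply(a_s, grp, min)
        a_e2 <- tapply(a_e, grp, max)
        fam <- tapply(fam, grp, `[`, 1L)
        a_e <- a_e2
      }
      tibble(chrom = dc$chrom[1], start = as.numeric(a_s),
             end = as.numeric(a_e), class = cls, family = as.character(fam))
    }))
  })
  res <- dplyr::bind_rows(out)
  res[order(res$class, res$chrom, res$start), , drop = FALSE]
}

#' Standardize breakpoints into analysis windows
#'
#' Reference-side windows are `breakpoint_window` bp centred on each
#' breakpoint midpoint (clipped to the scaffold). Query-side windows are two
#' `query_window`-sized intervals per breakpoint, each starting at the last
#' aligned query coordinate of a flanking block and extending towards the
#' nearer scaffold end (the theoretical point of breakage); windows running
#' past the scaffold end become the terminal `query_window`. Query-side
#' breakpoints further than `internal_cutoff` from both scaffold ends are
#' excluded as internal, duplicate windows at one scaffold end collapse to
#' the outermost representative, and events flagged ambiguous/unresolved
#' are dropped when a `final_type` column is present.
#'
#' @param events Event/breakpoint tibble. Reference side needs `ref`,
#'   `start`, `end`; query side needs `left_query`, `right_query`,
#'   `left_q_edge`, `right_q_edge`.
#' @param lengths Length tibble of the scaffolds the windows live on
#'   (reference scaffolds for `side = "reference"`, query scaffolds
#'   otherwise).
#' @param thresholds A [thresholds()] bundle.
#' @param side `"reference"` or `"query"`.
#' @return Tibble: `chrom`, `start`, `end`, `event_id`.
#' @export
standardize_breakpoints <- function(events, lengths, thresholds,
                                    side = c("reference", "query")) {
  side <- match.arg(side)
  assert_cols(lengths, c("chrom", "length"), "lengths")
  ev <- events
  if ("final_type" %in% names(ev)) {
    ev <- ev[!ev$final_type %in% c("ambiguous", "unresolved"), , drop = FALSE]
  }
  if (!"event_id" %in% names(ev)) ev$event_id <- seq_len(nrow(ev))
  Lmap <- stats::setNames(lengths$length, lengths$chrom)
  if (side == "reference") {
    assert_cols(ev, c("ref", "start", "end"), "events")
    if (!all(ev$ref %in% names(Lmap))) {
      ks_abort("missing scaffold length for a reference window",
               "input_error")
    }
    w <- thresholds$breakpoint_window
    mid <- floor((ev$start + ev$end) / 2)
    L <- unname(Lmap[ev$ref])
    out <- tibble(
      chrom = ev$ref,
      start = pmax(0, mid - w / 2),
      end = pmin(L, mid + w / 2),
      event_id = ev$event_id
    )
    return(out[out$end > out$start, , drop = FALSE])
  }
  assert_cols(ev, c("left_query", "right_query", "left_q_edge",
                    "right_q_edge"), "events")
  qw <- thresholds$query_window
  cutoff <- thresholds$internal_cutoff
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    for (sd in c("left", "right")) {
      scaf <- ev[[paste0(sd, "_query")]][i]
      edge <- ev[[paste0(sd, "_q_edge")]][i]
      if (is.na(scaf) || is.na(edge)) next
      if (!scaf %in% names(Lmap)) {
        ks_abort("missing scaffold length for a query window", "input_error")
      }
      L <- Lmap[[scaf]]
      d_end <- min(edge, L - edge)
      if (d_end > cutoff) next # internal breakpoint
      towards_right <- (L - edge) <= edge
      if (towards_right) {
        s <- edge; e <- edge + qw
        if (e > L) { s <- max(0, L - qw); e <- L }
        end_side <- "right"
      } else {
        e <- edge; s <- edge - qw
        if (s < 0) { s <- 0; e <- min(qw, L) }
        end_side <- "left"
      }
      rows[[length(rows) + 1L]] <- tibble(
        chrom = scaf, start = s, end = e, event_id = ev$event_id[i],
        end_side = end_side, dist = if (end_side == "right") L - e else s
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  event_id = integer()))
  }
  res <- dplyr::bind_rows(rows)
  # collapse duplicate windows per scaffold end to the outermost one
  res <- res |>
    dplyr::group_by(chrom, end_side) |>
    dplyr::slice_min(dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(chrom, start, end, event_id)
  res[res$end > res$start, , drop = FALSE]
}

#' Mean element density across windows
#'
#' @param windows Tibble: `chrom`, `start`, `end` (non-empty, positive
#'   widths).
#' @param track Element track tibble (`chrom`, `start`, `end`); merged
#'   internally.
#' @return Mean over windows of covered bp / window bp, in \[0, 1\].
#' @export
mean_density <- function(windows, track) {
  assert_cols(windows, c("chrom", "start", "end"), "windows")
  if (nrow(windows) == 0L) {
    ks_abort("windows must be non-empty", "input_error")
  }
  w <- windows$end - windows$start
  if (any(w <= 0)) ks_abort("zero-length window", "input_error")
  idx <- iv_index(track[, c("chrom", "start", "end")])
  cov <- iv_covered(idx, windows$chrom, windows$start, windows$end)
  mean(cov / w)
}

#' Resampling enrichment test for one element class
#'
#' Compares the observed mean density of an element track across the given
#' windows to a null distribution obtained by repeatedly drawing random
#' non-overlapping window sets of the same sizes and number from the
#' genome, excluding the observed breakpoint windows. The two-tailed
#' empirical p doubles the smaller add-one-corrected tail and is capped
#' at 1.
#'
#' @param windows Observed windows (`chrom`, `start`, `end`).
#' @param track Element track for one class.
#' @param lengths Scaffold length tibble.
#' @param n_iter Resampling iterations.
#' @param seed Integer seed.
#' @param exclude Regions the null windows must avoid; defaults to the
#'   observed windows.
#' @param class Label stored in the result.
#' @param max_retry Redraw attempts per iteration before a placement error.
#' @return A `karyo_enrichment`: observed and null mean densities, sd,
#'   two-tailed `p`, `direction`, and the null draws.
#' @export
resample_test <- function(windows, track, lengths, n_iter = 2000,
                          seed = 1, exclude = windows, class = NA_character_,
                          max_retry = 1000) {
  assert_cols(lengths, c("chrom", "length"), "lengths")
  if (n_iter < 1) ks_abort("n_iter must be >= 1", "input_error")
  observed <- mean_density(windows, track)
  widths <- round(windows$end - windows$start)
  k <- length(widths)
  L <- round(lengths$length)
  excl <- tibble(chrom = exclude$chrom, start = exclude$start,
                 end = exclude$end)
  track_idx <- iv_index(track[, c("chrom", "start", "end")])
  withr::with_seed(seed, {
    chrom_mat <- matrix("", n_iter, k)
    start_mat <- matrix(0, n_iter, k)
    draw_slot <- function(j, n) {
      w <- widths[j]
      valid <- which(L >= w)
      if (length(valid) == 0L) {
        ks_abort("window larger than every scaffold", "placement_error")
      }
      slots <- L[valid] - w + 1
      ci <- valid[sample.int(length(valid), n, replace = TRUE, prob = slots)]
      starts <- floor(stats::runif(n) * (L[ci] - w + 1))
      list(chrom = lengths$chrom[ci], start = starts)
    }
    for (j in seq_len(k)) {
      d <- draw_slot(j, n_iter)
      chrom_mat[, j] <- d$chrom
      start_mat[, j] <- d$start
      # redraw placements that hit the excluded regions
      for (try in seq_len(max_retry)) {
        bad <- iv_overlaps_any(chrom_mat[, j], start_mat[, j],
                               start_mat[, j] + widths[j], excl, tol = 0)
        if (!any(bad)) break
        if (try == max_retry) {
          ks_abort("could not place null windows outside excluded regions",
                   "placement_error")
        }
        d <- draw_slot(j, sum(bad))
        chrom_mat[bad, j] <- d$chrom
        start_mat[bad, j] <- d$start
      }
    }
    # enforce non-overlap within each iteration (rare at genome scale)
    if (k > 1L) {
      for (try in seq_len(max_retry)) {
        bad_iter <- overlapping_iterations(chrom_mat, start_mat, widths)
        if (length(bad_iter) == 0L) break
        if (try == max_retry) {
          ks_abort("could not draw non-overlapping window sets",
                   "placement_error")
        }
        for (j in seq_len(k)) {
          d <- draw_slot(j, length(bad_iter))
          repeat {
            bad <- iv_overlaps_any(d$chrom, d$start, d$start + widths[j],
                                   excl, tol = 0)
            if (!any(bad)) break
            rd <- draw_slot(j, sum(bad))
            d$chrom[bad] <- rd$chrom; d$start[bad] <- rd$start
          }
          chrom_mat[bad_iter, j] <- d$chrom
          start_mat[bad_iter, j] <- d$start
        }
      }
    }
    dens <- matrix(
      iv_covered(track_idx, as.vector(chrom_mat), as.vector(start_mat),
                 as.vector(start_mat) + rep(widths, each = n_iter)) /
        rep(widths, each = n_iter),
      n_iter, k
    )
    null_means <- rowMeans(dens)
    p <- min(1, 2 * min(sum(null_means <= observed) + 1,
                        sum(null_means >= observed) + 1) / (n_iter + 1))
    structure(list(
      class = class, n_windows = k, observed = observed,
      null_mean = mean(null_means), null_sd = stats::sd(null_means),
      p = p,
      direction = if (observed >= mean(null_means)) "enriched" else "depleted",
      null_means = null_means, n_iter = n_iter
    ), class = "karyo_enrichment")
  })
}

overlapping_iterations <- function(chrom_mat, start_mat, widths) {
  n_iter <- nrow(chrom_mat); k <- ncol(chrom_mat)
  bad <- logical(n_iter)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      hit <- chrom_mat[, a] == chrom_mat[, b] &
        start_mat[, a] < start_mat[, b] + widths[b] &
        start_mat[, b] < start_mat[, a] + widths[a]
      bad <- bad | hit
    }
  }
  which(bad)
}

#' @export
print.karyo_enrichment <- function(x, ...) {
  cat(sprintf(
    "<karyo_enrichment> %s: observed %.4f vs null %.4f (sd %.4f); two-tailed p = %.4g (%s)\n",
    x$class %||% "?", x$observed, x$null_mean, x$null_sd, x$p, x$direction))
  invisible(x)
}

#' Enrichment tests across element classes with FDR control
#'
#' Runs [resample_test()] per element class and applies Benjamini-Hochberg
#' adjustment across the classes of this window set (per set type, matching
#' separate reference/query and fusion/fission panels).
#'
#' @param windows Observed windows.
#' @param elements Element annotation tibble (all classes); merged
#'   internally.
#' @param lengths Scaffold length tibble.
#' @param classes Classes to test; default all present.
#' @param n_iter,seed Passed to [resample_test()] (per-class streams are
#'   derived from `seed`).
#' @param set_type Label (e.g. `"fusion-reference"`).
#' @return Tibble of class `karyo_enrichment_set`: one row per class with
#'   observed/null densities, raw and BH-adjusted p, direction.
#' @export
breakpoint_enrichment <- function(windows, elements, lengths,
                                  classes = NULL, n_iter = 2000, seed = 1,
                                  set_type = NA_character_) {
  track <- merge_elements(elements)
  classes <- classes %||% sort(unique(track$class))
  res <- lapply(seq_along(classes), function(i) {
    tr <- track[track$class == classes[i], , drop = FALSE]
    r <- resample_test(windows, tr, lengths, n_iter = n_iter,
                       seed = seed + i, class = classes[i])
    tibble(set_type = set_type, class = classes[i],
           n_windows = r$n_windows, observed = r$observed,
           null_mean = r$null_mean, null_sd = r$null_sd,
           p = r$p, direction = r$direction)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("karyo_enrichment_set", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, in input order.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    ks_abort("p-values must lie in (0, 1]", "input_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Telomere-associated LINE screen
#'
#' Identifies LINE families over-represented in the terminal
#' `telomeric_region` of scaffolds with a one-sided Fisher's exact test
#' (family vs. all other LINEs, telomeric vs. rest), BH-adjusted. A family
#' is flagged when adjusted p < `alpha`, its telomeric element count is at
#' least the number of telomeres (`2 *` scaffold count by default), and it
#' is present in the terminal regions of at least half of the scaffolds.
#' When fusion windows are supplied, the summed fraction of flagged-family
#' bp among all LINE bp inside those windows is reported.
#'
#' @param track LINE element track with a `family` column (e.g. from
#'   [merge_elements()]).
#' @param lengths Scaffold length tibble.
#' @param thresholds A [thresholds()] bundle (`telomeric_region` is used).
#' @param alpha Significance level on adjusted p.
#' @param n_telomeres Telomere count criterion; default
#'   `2 * nrow(lengths)`.
#' @param fusion_windows Optional fusion breakpoint windows for the
#'   flagged-fraction computation.
#' @return A `karyo_telo_screen`: `families` tibble (counts, p, adjusted p,
#'   criteria flags), `flagged` family names, `fraction` (flagged-family
#'   share of LINE bp in fusion windows, `NA` without windows), and
#'   `nonflagged_track` for re-running the LINE enrichment without the
#'   flagged subset.
#' @export
telomeric_line_screen <- function(track, lengths, thresholds,
                                  alpha = 0.05, n_telomeres = NULL,
                                  fusion_windows = NULL) {
  assert_cols(track, c("chrom", "start", "end", "family"), "track")
  assert_cols(lengths, c("chrom", "length"), "lengths")
  tr <- track[!is.na(track$family), , drop = FALSE]
  if (nrow(tr) == 0L) {
    warn("no LINE families in track; empty telomeric screen")
    return(structure(list(
      families = tibble(family = character(), telo = integer(),
                        elsewhere = integer(), p = double(),
                        p_adj = double(), n_scaffolds = integer(),
                        flagged = logical()),
      flagged = character(), fraction = NA_real_, nonflagged_track = tr
    ), class = "karyo_telo_screen"))
  }
  n_telomeres <- n_telomeres %||% (2L * nrow(lengths))
  tz <- thresholds$telomeric_region
  zones <- tibble(
    chrom = rep(lengths$chrom, 2L),
    start = c(rep(0, nrow(lengths)), lengths$length - tz),
    end = c(pmin(tz, lengths$length), lengths$length)
  )
  telo <- iv_overlaps_any(tr$chrom, tr$start, tr$end, zones, tol = 0)
  fams <- sort(unique(tr$family))
  tot_telo <- sum(telo); tot_all <- nrow(tr)
  rows <- lapply(fams, function(f) {
    in_f <- tr$family == f
    a <- sum(in_f & telo); b <- sum(in_f & !telo)
    c_ <- tot_telo - a; d <- (tot_all - sum(in_f)) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    n_scaf <- length(unique(tr$chrom[in_f & telo]))
    tibble(family = f, telo = a, elsewhere = b, p = p, n_scaffolds = n_scaf)
  })
  families <- dplyr::bind_rows(rows)
  families$p_adj <- bh_adjust(families$p)
  families$flagged <- families$p_adj < alpha &
    families$telo >= n_telomeres &
    families$n_scaffolds >= nrow(lengths) / 2
  flagged <- families$family[families$flagged]
  fraction <- NA_real_
  if (!is.null(fusion_windows) && nrow(fusion_windows) > 0L) {
    idx_all <- iv_index(tr[, c("chrom", "start", "end")])
    total_bp <- sum(iv_covered(idx_all, fusion_windows$chrom,
                               fusion_windows$start, fusion_windows$end))
    if (total_bp > 0) {
      sub <- tr[tr$family %in% flagged, , drop = FALSE]
      flag_bp <- if (nrow(sub) == 0L) 0 else
        sum(iv_covered(iv_index(sub[, c("chrom", "start", "end")]),
                       fusion_windows$chrom, fusion_windows$start,
                       fusion_windows$end))
      fraction <- flag_bp / total_bp
    }
  }
  structure(list(
    families = families, flagged = flagged, fraction = fraction,
    nonflagged_track = tr[!tr$family %in% flagged, , drop = FALSE]
  ), class = "karyo_telo_screen")
}

#' @export
print.karyo_telo_screen <- function(x, ...) {
  cat(sprintf("<karyo_telo_screen> %d families tested, %d flagged",
              nrow(x$families), length(x$flagged)))
  if (!is.na(x$fraction)) {
    cat(sprintf("; flagged share of LINE bp in fusion windows: %.2f%%",
                100 * x$fraction))
  }
  cat("\n")
  invisible(x)
}
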