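# Karyotype evolution along a fixed 4-taxon species tree.
#
# Topology: ((pop1, pop2), sister), outgroup — two conspecific populations,
# their sister species, and a more distant congener. The ancestral genome
# itself doubles as the ancestral-karyotype reference used for polarization
# (the role an outgroup family with a conserved karyotype plays in real
# comparative work). Branch event counts are explicit inputs, not rates, so
# every downstream stage can be scored against exact ground truth.

#' Fixed species tree for the simulator
#'
#' @param pop1,pop2,sister,outgroup Tip labels.
#' @return A `karyo_tree`: tip labels, branch table, and the tip set below
#'   each branch (used to translate sharing patterns into branch
#'   assignments).
#' @export
karyo_tree <- function(pop1 = "pop1", pop2 = "pop2",
                       sister = "sister", outgroup = "outgroup") {
  tips <- c(pop1 = pop1, pop2 = pop2, sister = sister, outgroup = outgroup)
  if (anyDuplicated(tips)) ks_abort("tip labels must be unique", "input_error")
  clades <- list(
    pop1 = pop1, pop2 = pop2, sister = sister, outgroup = outgroup,
    pop_stem = c(pop1, pop2),
    ingroup_stem = c(pop1, pop2, sister)
  )
  structure(list(
    tips = tips,
    branches = c("outgroup", "ingroup_stem", "sister",
                 "pop_stem", "pop1", "pop2"),
    clades = clades,
    # parent branch path from root to each tip (event accumulation order)
    paths = list(
      outgroup = "outgroup",
      sister = c("ingroup_stem", "sister"),
      pop1 = c("ingroup_stem", "pop_stem", "pop1"),
      pop2 = c("ingroup_stem", "pop_stem", "pop2")
    )
  ), class = "karyo_tree")
}

# Branch whose descendant tip set equals `labels`, or NA.
branch_for_clade <- function(tree, labels) {
  for (b in names(tree$clades)) {
    if (setequal(tree$clades[[b]], labels)) return(b)
  }
  NA_character_
}

event_types <- c("fission", "fusion", "inversion",
                 "reciprocal_translocation", "nonreciprocal_translocation")

#' Evolve a karyotype along the species tree
#'
#' Applies the requested number of structural events per branch, in random
#' order within each branch, and records every event with exact coordinates
#' in a replayable ground-truth log. Break positions are drawn uniformly at
#' least `config$break_margin` from chromosome ends and at least
#' `config$min_event_spacing` (in ancestral coordinates) from every
#' previously used event locus; an ancestral chromosome end is used in at
#' most one fusion junction across the whole tree.
#'
#' @param ancestral A `karyo_genome` from [simulate_ancestral_genome()].
#' @param events Data frame with a `branch` column (subset of
#'   `karyo_tree()$branches`) and any of the count columns `fissions`,
#'   `fusions`, `inversions`, `reciprocal_translocations`,
#'   `nonreciprocal_translocations`.
#' @param config The [sim_config()] used for the ancestral genome.
#' @param tree A [karyo_tree()].
#' @return A `karyo_sim` list: `ancestral`, `tips` (named list of
#'   `karyo_genome`), `log` (ground-truth event tibble), `tree`, `config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 10, seed = 4)
#' anc <- simulate_ancestral_genome(cfg)
#' sim <- evolve_karyotype(anc, data.frame(branch = "pop1", fusions = 3), cfg)
#' nrow(sim$tips$pop1$chrom_lengths)  # 7
#' @export
evolve_karyotype <- function(ancestral, events, config, tree = karyo_tree()) {
  assert_cols(events, "branch")
  bad <- setdiff(events$branch, tree$branches)
  if (length(bad) > 0) {
    ks_abort(paste0("unknown branch: ", paste(bad, collapse = ", ")),
             "simulation_error")
  }
  count_cols <- c(fission = "fissions", fusion = "fusions",
                  inversion = "inversions",
                  reciprocal_translocation = "reciprocal_translocations",
                  nonreciprocal_translocation = "nonreciprocal_translocations")
  for (cc in count_cols) {
    if (!cc %in% names(events)) events[[cc]] <- rep(0L, nrow(events))
  }

  state <- new.env(parent = emptyenv())
  state$used_loci <- ancestral$anc_lengths |>
    # chromosome ends are loci from the start (margins also protect them)
    (\(d) tibble(anc_chrom = rep(d$anc_chrom, 2L),
                 anc_pos = c(rep(0, nrow(d)), d$length)))()
  state$used_ends <- character()
  # unordered ancestral-chromosome pairs already co-resident on one
  # chromosome in some genome: no second lineage may join such a pair
  # independently (single-scaffold block merging could not see the second
  # junction, so those histories are unidentifiable by construction)
  state$co_pairs <- character()
  state$log <- list()

  branch_order <- c("outgroup", "ingroup_stem", "sister",
                    "pop_stem", "pop1", "pop2")
  withr::with_seed(config$seed + 1L, {
    genomes <- list(root = ancestral)
    parent_of <- c(outgroup = "root", ingroup_stem = "root",
                   sister = "ingroup_stem", pop_stem = "ingroup_stem",
                   pop1 = "pop_stem", pop2 = "pop_stem")
    for (br in branch_order) {
      g <- genomes[[parent_of[[br]]]]
      row <- events[events$branch == br, , drop = FALSE]
      if (nrow(row) == 1L) {
        seq_types <- rep(names(count_cols),
                         times = unlist(row[1, count_cols]))
        if (length(seq_types) > 1L) seq_types <- sample(seq_types)
        for (i in seq_along(seq_types)) {
          g <- apply_random_event(g, seq_types[i], br, i, config, state)
        }
      }
      genomes[[br]] <- g
    }
    tips <- list()
    for (role in names(tree$tips)) {
      tg <- genomes[[role]]
      tg$species <- unname(tree$tips[[role]])
      tips[[tree$tips[[role]]]] <- tg
    }
    log <- dplyr::bind_rows(state$log)
    structure(list(ancestral = ancestral, tips = tips, log = log,
                   tree = tree, config = config),
              class = "karyo_sim")
  })
}

#' Simulate an ancestral genome and evolve it in one call
#'
#' @inheritParams evolve_karyotype
#' @return A `karyo_sim`; see [evolve_karyotype()].
#' @export
simulate_karyotypes <- function(config, events, tree = karyo_tree()) {
  anc <- simulate_ancestral_genome(config)
  evolve_karyotype(anc, events, config, tree)
}

# ---- event machinery ------------------------------------------------------

anc_point <- function(g, chrom, pos) {
  seg <- g$segments
  s <- seg[seg$chrom == chrom & seg$start <= pos & seg$end > pos, , drop = FALSE]
  if (nrow(s) == 0L) { # pos == chromosome length
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    s <- s[which.max(s$end), , drop = FALSE]
  }
  if (s$strand == 1L) {
    c(anc_chrom = s$anc_chrom, anc_pos = s$anc_start + (pos - s$start))
  } else {
    c(anc_chrom = s$anc_chrom, anc_pos = s$anc_end - (pos - s$start))
  }
}

locus_free <- function(state, anc_chrom, anc_pos, spacing) {
  u <- state$used_loci
  !any(u$anc_chrom == anc_chrom & abs(u$anc_pos - anc_pos) < spacing)
}

register_locus <- function(state, anc_chrom, anc_pos) {
  state$used_loci <- dplyr::bind_rows(
    state$used_loci, tibble(anc_chrom = as.integer(anc_chrom),
                            anc_pos = as.numeric(anc_pos)))
}

# Draw an interior break position respecting margin and spacing.
sample_break <- function(g, config, state, branch,
                         chrom = NULL, lo = NULL, hi = NULL,
                         room_right = 0) {
  m <- config$break_margin
  cl <- g$chrom_lengths
  for (try in 1:500) {
    w <- pmax(cl$length - 2 * m - room_right, 0)
    if (is.null(chrom) && sum(w) == 0) break
    ch <- chrom %||% cl$chrom[sample.int(nrow(cl), 1L, prob = w)]
    L <- cl$length[cl$chrom == ch]
    if (L <= 2 * m + room_right) next
    a <- max(lo %||% m, m)
    b <- min(hi %||% (L - m - room_right), L - m - room_right)
    if (b <= a) next
    pos <- round(stats::runif(1, a, b))
    ap <- anc_point(g, ch, pos)
    if (locus_free(state, ap["anc_chrom"], ap["anc_pos"],
                   config$min_event_spacing)) {
      register_locus(state, ap["anc_chrom"], ap["anc_pos"])
      return(list(chrom = ch, pos = pos, anc = ap))
    }
  }
  ks_abort(paste0("could not place a break on branch '", branch,
                  "' (genome too crowded)"), "simulation_error")
}

end_key <- function(e) paste0(e[["anc_chrom"]], ":", e[["side"]])

chrom_anc_set <- function(g, chrom) {
  unique(g$segments$anc_chrom[g$segments$chrom == chrom])
}

pair_keys <- function(sx, sy) {
  grid <- expand.grid(a = sx, b = sy)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  unique(paste0(pmin(grid$a, grid$b), "~", pmax(grid$a, grid$b)))
}

register_co_pairs <- function(state, sx, sy) {
  state$co_pairs <- union(state$co_pairs, pair_keys(sx, sy))
}

eligible_fusion_ends <- function(g, state) {
  seg <- g$segments # sorted by chrom, ord
  Lmap <- stats::setNames(g$anc_lengths$length, g$anc_lengths$anc_chrom)
  one_side <- function(idx, side) {
    s <- seg[idx, , drop = FALSE]
    outer_is_head <- (side == "left") == (s$strand == 1L)
    Lanc <- unname(Lmap[as.character(s$anc_chrom)])
    is_head_end <- outer_is_head & s$anc_start == 0
    is_tail_end <- !outer_is_head & s$anc_end == Lanc
    keep <- is_head_end | is_tail_end
    anc_side <- ifelse(is_head_end, "head", "tail")[keep]
    tibble::new_tibble(list(
      chrom = s$chrom[keep], side = rep(side, sum(keep)),
      anc_chrom = s$anc_chrom[keep], anc_side = anc_side
    ), nrow = sum(keep))
  }
  res <- dplyr::bind_rows(
    one_side(which(!duplicated(seg$chrom)), "left"),
    one_side(which(!duplicated(seg$chrom, fromLast = TRUE)), "right")
  )
  res[!paste0(res$anc_chrom, ":", res$anc_side) %in% state$used_ends, ,
      drop = FALSE]
}

split_segments_at <- function(g, chrom, pos) {
  seg <- g$segments
  sel <- seg$chrom == chrom & seg$start < pos & seg$end > pos
  if (any(sel)) {
    s <- seg[sel, , drop = FALSE]
    off <- pos - s$start
    if (s$strand == 1L) {
      left <- s; left$anc_end <- s$anc_start + off
      right <- s; right$anc_start <- s$anc_start + off
    } else {
      left <- s; left$anc_start <- s$anc_end - off
      right <- s; right$anc_end <- s$anc_end - off
    }
    right$ord <- s$ord + 0.5
    seg <- dplyr::bind_rows(seg[!sel, , drop = FALSE], left, right)
  }
  seg <- seg[order(seg$chrom, seg$ord), , drop = FALSE]
  seg$ord <- stats::ave(seq_len(nrow(seg)), seg$chrom, FUN = seq_along)
  g$segments <- seg
  refresh_local_coords(g)
}

flip_chromosome_rows <- function(rows) {
  rows <- rows[order(rows$ord, decreasing = TRUE), , drop = FALSE]
  rows$strand <- -rows$strand
  rows$ord <- seq_len(nrow(rows))
  rows
}

telo_row <- function(g, chrom) {
  g$telomeres[g$telomeres$chrom == chrom, , drop = FALSE]
}

do_fission <- function(g, chrom, pos) {
  g <- split_segments_at(g, chrom, pos)
  seg <- g$segments
  a <- g$next_id; b <- g$next_id + 1L
  sel <- seg$chrom == chrom
  left <- seg$end <= pos
  seg$chrom[sel & left] <- a
  seg$chrom[sel & !left] <- b
  old <- telo_row(g, chrom)
  g$telomeres <- dplyr::bind_rows(
    g$telomeres[g$telomeres$chrom != chrom, , drop = FALSE],
    tibble(chrom = a, left = old$left, right = FALSE),
    tibble(chrom = b, left = FALSE, right = old$right)
  )
  g$segments <- seg
  g$next_id <- g$next_id + 2L
  g <- refresh_local_coords(g)
  # renumber ord within the two new chromosomes
  g$segments$ord <- stats::ave(seq_len(nrow(g$segments)),
                               g$segments$chrom, FUN = seq_along)
  refresh_local_coords(g)
}

do_fusion <- function(g, chrom_x, end_x, chrom_y, end_y, retain, state = NULL) {
  seg <- g$segments
  x <- seg[seg$chrom == chrom_x, , drop = FALSE][order(seg$ord[seg$chrom == chrom_x]), ]
  y <- seg[seg$chrom == chrom_y, , drop = FALSE][order(seg$ord[seg$chrom == chrom_y]), ]
  tx <- telo_row(g, chrom_x); ty <- telo_row(g, chrom_y)
  x_left <- tx$left; x_right <- tx$right
  y_left <- ty$left; y_right <- ty$right
  if (end_x == "left") { x <- flip_chromosome_rows(x); tmp <- x_left; x_left <- x_right; x_right <- tmp }
  if (end_y == "right") { y <- flip_chromosome_rows(y); tmp <- y_left; y_left <- y_right; y_right <- tmp }
  new_id <- g$next_id
  x$chrom <- new_id; y$chrom <- new_id
  y$ord <- y$ord + max(x$ord)
  rest <- seg[!(seg$chrom %in% c(chrom_x, chrom_y)), , drop = FALSE]
  g$segments <- dplyr::bind_rows(rest, x, y)
  g$telomeres <- dplyr::bind_rows(
    g$telomeres[!(g$telomeres$chrom %in% c(chrom_x, chrom_y)), , drop = FALSE],
    tibble(chrom = new_id, left = x_left, right = y_right)
  )
  g$next_id <- g$next_id + 1L
  if (retain) {
    # anchor the remnant to the ancestral end buried at the junction
    last_x <- x[which.max(x$ord), ]
    side <- if (last_x$strand == 1L) "tail" else "head"
    g$remnants <- dplyr::bind_rows(
      g$remnants, tibble(anc_chrom = last_x$anc_chrom, side = side))
  }
  refresh_local_coords(g)
}

do_inversion <- function(g, chrom, a, b) {
  g <- split_segments_at(g, chrom, a)
  g <- split_segments_at(g, chrom, b)
  seg <- g$segments
  sel <- seg$chrom == chrom & seg$start >= a & seg$end <= b
  inner <- seg[sel, , drop = FALSE]
  inner <- inner[order(inner$ord), , drop = FALSE]
  inv <- inner
  inv$anc_chrom <- rev(inner$anc_chrom)
  inv$anc_start <- rev(inner$anc_start)
  inv$anc_end <- rev(inner$anc_end)
  inv$strand <- -rev(inner$strand)
  seg[sel, c("anc_chrom", "anc_start", "anc_end", "strand")] <-
    inv[, c("anc_chrom", "anc_start", "anc_end", "strand")]
  g$segments <- seg
  refresh_local_coords(g)
}

do_reciprocal <- function(g, c1, p1, c2, p2) {
  g <- split_segments_at(g, c1, p1)
  g <- split_segments_at(g, c2, p2)
  seg <- g$segments
  h1 <- seg$chrom == c1 & seg$end <= p1
  t1 <- seg$chrom == c1 & seg$end > p1
  h2 <- seg$chrom == c2 & seg$end <= p2
  t2 <- seg$chrom == c2 & seg$end > p2
  a <- g$next_id; b <- g$next_id + 1L
  seg$chrom[h1] <- a; seg$chrom[t2] <- a
  seg$chrom[h2] <- b; seg$chrom[t1] <- b
  g$segments <- seg
  t1r <- telo_row(g, c1); t2r <- telo_row(g, c2)
  g$telomeres <- dplyr::bind_rows(
    g$telomeres[!(g$telomeres$chrom %in% c(c1, c2)), , drop = FALSE],
    tibble(chrom = a, left = t1r$left, right = t2r$right),
    tibble(chrom = b, left = t2r$left, right = t1r$right)
  )
  g$next_id <- g$next_id + 2L
  # rebuild ord: heads keep order, appended tails follow
  seg <- g$segments
  for (nc in c(a, b)) {
    rows <- which(seg$chrom == nc)
    # head rows come from the chromosome whose start coordinate was 0
    ord_key <- seg$start[rows]
    head_from_c1 <- if (nc == a) h1 else h2
    is_head <- head_from_c1[rows]
    seg$ord[rows][order(!is_head, ord_key)] <- seq_along(rows)
  }
  g$segments <- seg
  refresh_local_coords(g)
}

do_nonreciprocal <- function(g, src, a, b, dst, p) {
  g <- split_segments_at(g, src, a)
  g <- split_segments_at(g, src, b)
  g <- split_segments_at(g, dst, p)
  seg <- g$segments
  piece <- seg$chrom == src & seg$start >= a & seg$end <= b
  src_rest <- seg$chrom == src & !piece
  dst_head <- seg$chrom == dst & seg$end <= p
  dst_tail <- seg$chrom == dst & seg$start >= p
  ns <- g$next_id; nd <- g$next_id + 1L
  seg$chrom[src_rest] <- ns
  seg$chrom[dst_head | dst_tail] <- nd
  seg$chrom[piece] <- nd
  # order within nd: head (by start), piece (by ord), tail (by start)
  rows <- which(seg$chrom == nd)
  grp <- ifelse(dst_head[rows], 1L, ifelse(piece[rows], 2L, 3L))
  seg$ord[rows][order(grp, seg$start[rows])] <- seq_along(rows)
  rows_s <- which(seg$chrom == ns)
  seg$ord[rows_s][order(seg$start[rows_s])] <- seq_along(rows_s)
  ts <- telo_row(g, src); td <- telo_row(g, dst)
  g$telomeres <- dplyr::bind_rows(
    g$telomeres[!(g$telomeres$chrom %in% c(src, dst)), , drop = FALSE],
    tibble(chrom = ns, left = ts$left, right = ts$right),
    tibble(chrom = nd, left = td$left, right = td$right)
  )
  g$segments <- seg
  g$next_id <- g$next_id + 2L
  refresh_local_coords(g)
}

log_row <- function(branch, step, type, ...) {
  dots <- list(...)
  base <- tibble(
    branch = branch, step = step, type = type,
    chrom_a = NA_integer_, chrom_b = NA_integer_,
    pos_a = NA_real_, pos_b = NA_real_, pos_c = NA_real_,
    end_a = NA_character_, end_b = NA_character_, retain = NA,
    anc_chrom_a = NA_integer_, anc_pos_a = NA_real_,
    anc_chrom_b = NA_integer_, anc_pos_b = NA_real_
  )
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

apply_random_event <- function(g, type, branch, step, config, state) {
  if (type == "fission") {
    if (nrow(g$chrom_lengths) < 1L ||
        max(g$chrom_lengths$length) <= 2 * config$break_margin) {
      ks_abort(paste0("no chromosome long enough to fission on branch '",
                      branch, "'"), "simulation_error")
    }
    br <- sample_break(g, config, state, branch)
    state$log[[length(state$log) + 1L]] <- log_row(
      branch, step, "fission", chrom_a = br$chrom, pos_a = br$pos,
      anc_chrom_a = as.integer(br$anc[["anc_chrom"]]),
      anc_pos_a = unname(br$anc[["anc_pos"]]))
    do_fission(g, br$chrom, br$pos)
  } else if (type == "fusion") {
    if (nrow(g$chrom_lengths) < 2L) {
      ks_abort(paste0("cannot fuse below one chromosome on branch '",
                      branch, "'"), "simulation_error")
    }
    cand <- eligible_fusion_ends(g, state)
    if (nrow(cand) < 2L || length(unique(cand$chrom)) < 2L) {
      ks_abort(paste0("no eligible ancestral chromosome ends left to fuse ",
                      "on branch '", branch, "'"), "simulation_error")
    }
    ok <- FALSE
    for (try in 1:200) {
      i <- sample.int(nrow(cand), 1L)
      e1 <- cand[i, ]
      cand2 <- cand[cand$chrom != e1$chrom, , drop = FALSE]
      e2 <- cand2[sample.int(nrow(cand2), 1L), ]
      sx <- chrom_anc_set(g, e1$chrom)
      sy <- chrom_anc_set(g, e2$chrom)
      # partners must not share ancestral material (re-joining fission
      # products of one chromosome is invisible to scaffold-identity
      # block merging) nor recreate a pair joined in another lineage
      if (length(intersect(sx, sy)) == 0L &&
          !any(pair_keys(sx, sy) %in% state$co_pairs)) { ok <- TRUE; break }
    }
    if (!ok) {
      ks_abort(paste0("no non-convergent fusion available on branch '",
                      branch, "'"), "simulation_error")
    }
    register_co_pairs(state, sx, sy)
    retain <- stats::runif(1) < config$telomere_retention_prob
    state$used_ends <- c(state$used_ends,
                         paste0(e1$anc_chrom, ":", e1$anc_side),
                         paste0(e2$anc_chrom, ":", e2$anc_side))
    # junction loci: protect both buried ends from nearby later events
    for (e in list(e1, e2)) {
      Lanc <- g$anc_lengths$length[g$anc_lengths$anc_chrom == e$anc_chrom]
      register_locus(state, e$anc_chrom,
                     if (e$anc_side == "head") 0 else Lanc)
    }
    state$log[[length(state$log) + 1L]] <- log_row(
      branch, step, "fusion",
      chrom_a = e1$chrom, end_a = e1$side,
      chrom_b = e2$chrom, end_b = e2$side, retain = retain,
      anc_chrom_a = e1$anc_chrom, anc_chrom_b = e2$anc_chrom)
    do_fusion(g, e1$chrom, e1$side, e2$chrom, e2$side, retain)
  } else if (type == "inversion") {
    br1 <- sample_break(g, config, state, branch,
                        room_right = 2 * config$min_event_spacing)
    L <- g$chrom_lengths$length[g$chrom_lengths$chrom == br1$chrom]
    span <- round(stats::runif(1, config$min_event_spacing, L / 3))
    hi <- min(br1$pos + span, L - config$break_margin)
    br2 <- sample_break(g, config, state, branch, chrom = br1$chrom,
                        lo = br1$pos + config$min_event_spacing, hi = hi)
    state$log[[length(state$log) + 1L]] <- log_row(
      branch, step, "inversion", chrom_a = br1$chrom,
      pos_a = br1$pos, pos_b = br2$pos,
      anc_chrom_a = as.integer(br1$anc[["anc_chrom"]]),
      anc_pos_a = unname(br1$anc[["anc_pos"]]))
    do_inversion(g, br1$chrom, min(br1$pos, br2$pos), max(br1$pos, br2$pos))
  } else if (type == "reciprocal_translocation") {
    if (nrow(g$chrom_lengths) < 2L) {
      ks_abort(paste0("need two chromosomes for a translocation on branch '",
                      branch, "'"), "simulation_error")
    }
    br1 <- sample_break(g, config, state, branch)
    repeat {
      br2 <- sample_break(g, config, state, branch)
      if (br2$chrom != br1$chrom) break
    }
    state$log[[length(state$log) + 1L]] <- log_row(
      branch, step, "reciprocal_translocation",
      chrom_a = br1$chrom, pos_a = br1$pos,
      chrom_b = br2$chrom, pos_b = br2$pos,
      anc_chrom_a = as.integer(br1$anc[["anc_chrom"]]),
      anc_pos_a = unname(br1$anc[["anc_pos"]]),
      anc_chrom_b = as.integer(br2$anc[["anc_chrom"]]),
      anc_pos_b = unname(br2$anc[["anc_pos"]]))
    old_next <- g$next_id
    g <- do_reciprocal(g, br1$chrom, br1$pos, br2$chrom, br2$pos)
    for (nc in setdiff(unique(g$segments$chrom), seq_len(old_next - 1L))) {
      s <- chrom_anc_set(g, nc)
      register_co_pairs(state, s, s)
    }
    g
  } else if (type == "nonreciprocal_translocation") {
    if (nrow(g$chrom_lengths) < 2L) {
      ks_abort(paste0("need two chromosomes for a translocation on branch '",
                      branch, "'"), "simulation_error")
    }
    br1 <- sample_break(g, config, state, branch,
                        room_right = 3 * config$min_event_spacing)
    L <- g$chrom_lengths$length[g$chrom_lengths$chrom == br1$chrom]
    span <- round(stats::runif(1, 2 * config$min_event_spacing, L / 4))
    hi <- min(br1$pos + span, L - config$break_margin)
    br2 <- sample_break(g, config, state, branch, chrom = br1$chrom,
                        lo = br1$pos + 2 * config$min_event_spacing, hi = hi)
    repeat {
      br3 <- sample_break(g, config, state, branch)
      if (br3$chrom != br1$chrom) break
    }
    state$log[[length(state$log) + 1L]] <- log_row(
      branch, step, "nonreciprocal_translocation",
      chrom_a = br1$chrom, pos_a = min(br1$pos, br2$pos),
      pos_b = max(br1$pos, br2$pos),
      chrom_b = br3$chrom, pos_c = br3$pos,
      anc_chrom_a = as.integer(br1$anc[["anc_chrom"]]),
      anc_pos_a = unname(br1$anc[["anc_pos"]]),
      anc_chrom_b = as.integer(br3$anc[["anc_chrom"]]),
      anc_pos_b = unname(br3$anc[["anc_pos"]]))
    old_next <- g$next_id
    g <- do_nonreciprocal(g, br1$chrom, min(br1$pos, br2$pos),
                          max(br1$pos, br2$pos), br3$chrom, br3$pos)
    for (nc in setdiff(unique(g$segments$chrom), seq_len(old_next - 1L))) {
      s <- chrom_anc_set(g, nc)
      register_co_pairs(state, s, s)
    }
    g
  } else {
    ks_abort(paste0("unknown event type: ", type), "simulation_error")
  }
}

#' Replay a ground-truth log from the ancestral genome
#'
#' Applies the logged events literally (no randomness); the result must
#' reproduce every tip genome exactly.
#'
#' @param ancestral The ancestral `karyo_genome`.
#' @param log The `log` tibble of a `karyo_sim`.
#' @param tree The `karyo_tree` used.
#' @return Named list of tip `karyo_genome`s.
#' @export
replay_log <- function(ancestral, log, tree = karyo_tree()) {
  parent_of <- c(outgroup = "root", ingroup_stem = "root",
                 sister = "ingroup_stem", pop_stem = "ingroup_stem",
                 pop1 = "pop_stem", pop2 = "pop_stem")
  genomes <- list(root = ancestral)
  for (br in c("outgroup", "ingroup_stem", "sister",
               "pop_stem", "pop1", "pop2")) {
    g <- genomes[[parent_of[[br]]]]
    rows <- log[log$branch == br, , drop = FALSE]
    if (nrow(rows) > 0) rows <- rows[order(rows$step), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      g <- switch(r$type,
        fission = do_fission(g, r$chrom_a, r$pos_a),
        fusion = do_fusion(g, r$chrom_a, r$end_a, r$chrom_b, r$end_b,
                           r$retain),
        inversion = do_inversion(g, r$chrom_a, min(r$pos_a, r$pos_b),
                                 max(r$pos_a, r$pos_b)),
        reciprocal_translocation =
          do_reciprocal(g, r$chrom_a, r$pos_a, r$chrom_b, r$pos_b),
        nonreciprocal_translocation =
          do_nonreciprocal(g, r$chrom_a, r$pos_a, r$pos_b,
                           r$chrom_b, r$pos_c)
      )
    }
    genomes[[br]] <- g
  }
  tips <- list()
  for (role in names(tree$tips)) {
    tg <- genomes[[role]]
    tg$species <- unname(tree$tips[[role]])
    tips[[tree$tips[[role]]]] <- tg
  }
  tips
}

#' Per-branch event counts of a ground-truth log
#'
#' @param log The `log` tibble of a `karyo_sim`.
#' @return Tibble: `branch`, `type`, `n`.
#' @export
summarize_log <- function(log) {
  if (nrow(log) == 0L) {
    return(tibble(branch = character(), type = character(), n = integer()))
  }
  log |>
    dplyr::count(branch, type, name = "n") |>
    dplyr::arrange(branch, type)
}
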