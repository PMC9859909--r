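# Genome representation for the karyotype simulator.
#
# A genome is a set of chromosomes, each an ordered list of segments of the
# ancestral genome (ancestral chromosome, ancestral interval, orientation).
# Element annotations are stored once in ancestral coordinates and projected
# into any descendant genome through its segment map, which makes base
# conservation automatic. Telomere state is a per-end flag plus a table of
# internal remnant anchors (ancestral chromosome ends buried by fusions).

new_genome <- function(species, segments, anc_lengths, anc_elements,
                       telomeres, remnants, next_id) {
  g <- structure(list(
    species = species,
    segments = segments,
    anc_lengths = anc_lengths,
    anc_elements = anc_elements,
    telomeres = telomeres,
    remnants = remnants,
    next_id = next_id
  ), class = "karyo_genome")
  refresh_local_coords(g)
}

# Recompute local 0-based half-open coordinates from segment order.
refresh_local_coords <- function(g) {
  seg <- g$segments
  seg <- seg[order(seg$chrom, seg$ord), , drop = FALSE]
  w <- seg$anc_end - seg$anc_start
  ends <- stats::ave(w, seg$chrom, FUN = cumsum)
  seg$start <- ends - w
  seg$end <- ends
  g$segments <- seg
  g$chrom_lengths <- seg |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(length = sum(anc_end - anc_start), .groups = "drop")
  g
}

#' @export
print.karyo_genome <- function(x, ...) {
  cat(sprintf(
    "<karyo_genome> species '%s': %d chromosomes, %s bp, %d segments\n",
    x$species, nrow(x$chrom_lengths),
    format(sum(x$chrom_lengths$length), big.mark = ","), nrow(x$segments)
  ))
  invisible(x)
}

#' Chromosome length table of a simulated genome
#'
#' @param genome A `karyo_genome`.
#' @param scaffold_names Use emitted scaffold names (`species_chrN`) rather
#'   than integer ids.
#' @return Tibble with `chrom` and `length`.
#' @export
chromosome_lengths <- function(genome, scaffold_names = TRUE) {
  out <- genome$chrom_lengths
  if (scaffold_names) out$chrom <- scaffold_name(genome, out$chrom)
  out
}

scaffold_name <- function(genome, chrom) {
  paste0(genome$species, "_chr", chrom)
}

#' Simulate an ancestral genome
#'
#' Draws chromosome lengths, places sequence-element annotations (CDS and
#' TE classes) to hit target genome fractions, and marks telomeres at every
#' chromosome end. Element placement is uniform except in terminal
#' "fusion zones", where classes listed in `fusion_site_enrichment` are
#' placed at a multiplied density; since fusions join chromosome ends, those
#' zones are exactly the sequence that later flanks fusion junctions.
#'
#' @param config A [sim_config()].
#' @return A `karyo_genome` whose chromosomes each consist of one ancestral
#'   segment, with telomere flags set at all ends.
#' @examples
#' g <- simulate_ancestral_genome(sim_config(n_chromosomes = 4, seed = 1))
#' chromosome_lengths(g)
#' @export
simulate_ancestral_genome <- function(config) {
  if (!inherits(config, "karyo_sim_config")) {
    ks_abort("config must be created by sim_config()", "configuration_error")
  }
  withr::with_seed(config$seed, {
    n <- config$n_chromosomes
    lens <- round(stats::rnorm(n, config$chromosome_length_mean,
                               config$chromosome_length_sd))
    lens <- pmax(lens, 4 * config$break_margin)
    segments <- tibble(
      chrom = seq_len(n), ord = 1L,
      anc_chrom = seq_len(n), anc_start = 0, anc_end = as.numeric(lens),
      strand = 1L
    )
    anc_lengths <- tibble(anc_chrom = seq_len(n), length = as.numeric(lens))
    elements <- place_elements(anc_lengths, config)
    telomeres <- tibble(
      chrom = seq_len(n), left = TRUE, right = TRUE
    )
    remnants <- tibble(anc_chrom = integer(), side = character())
    new_genome("ancestor", segments, anc_lengths, elements,
               telomeres, remnants, next_id = n + 1L)
  })
}

# Place annotation intervals in ancestral coordinates.
place_elements <- function(anc_lengths, config) {
  dens <- config$element_densities
  zone <- config$fusion_zone
  empty <- tibble(anc_chrom = integer(), start = double(), end = double(),
                  class = character(), family = character())
  out <- list(empty)
  total_bp <- sum(anc_lengths$length)
  for (cls in names(dens)) {
    d <- dens[[cls]]
    if (d <= 0) next
    f <- config$fusion_site_enrichment[cls]
    f <- if (is.null(f) || is.na(f)) 1 else unname(f)
    target <- d * total_bp
    kept <- empty[0, c("anc_chrom", "start", "end")]
    for (round in 1:8) {
      realized <- sum(kept$end - kept$start)
      if (realized >= 0.97 * target) break
      need <- target - realized
      k <- ceiling(need / config$element_length_mean * 1.15)
      cand <- draw_intervals(anc_lengths, k, config$element_length_mean,
                             zone_factor = f, zone = zone)
      kept <- greedy_disjoint(dplyr::bind_rows(kept, cand))
    }
    fam <- NA_character_
    res <- kept
    res$class <- cls
    if (cls == "LINE" && length(config$line_families) > 0) {
      res$family <- config$line_families[
        (seq_len(nrow(res)) - 1L) %% length(config$line_families) + 1L
      ]
    } else {
      res$family <- fam
    }
    out[[length(out) + 1L]] <- res
  }
  # Optional telomere-associated LINE family confined to terminal zones.
  if (!is.null(config$telomere_line_family) &&
      config$telomere_line_per_end > 0) {
    tz <- config$telomere_zone
    per <- config$telomere_line_per_end
    el <- config$element_length_mean
    tl <- purrr::pmap_dfr(anc_lengths, function(anc_chrom, length) {
      starts_l <- round(stats::runif(per, 0, max(tz - el, 1)))
      starts_r <- round(stats::runif(per, length - tz, length - el))
      tibble(
        anc_chrom = anc_chrom,
        start = c(starts_l, starts_r),
        end = pmin(c(starts_l, starts_r) + el, length)
      )
    })
    tl$class <- "LINE"
    tl$family <- config$telomere_line_family
    out[[length(out) + 1L]] <- tl
  }
  res <- dplyr::bind_rows(out)
  res[order(res$anc_chrom, res$start), , drop = FALSE]
}

# k candidate intervals of ~len bp, density multiplied by zone_factor within
# the two terminal zones of each chromosome.
draw_intervals <- function(anc_lengths, k, len, zone_factor = 1, zone = 0) {
  L <- anc_lengths$length
  zone <- pmin(zone, L / 4)
  w_int <- pmax(L - 2 * zone, 0)
  strata <- tibble(
    anc_chrom = rep(anc_lengths$anc_chrom, 3L),
    lo = c(rep(0, length(L)) + zone, rep(0, length(L)), L - zone),
    hi = c(L - zone, zone, L),
    w = c(w_int, zone * zone_factor, zone * zone_factor)
  )
  strata <- strata[strata$w > 0 & strata$hi > strata$lo, , drop = FALSE]
  idx <- sample.int(nrow(strata), k, replace = TRUE, prob = strata$w)
  lens <- pmax(25, round(stats::rexp(k, 1 / len)))
  lens <- pmin(lens, 5 * len)
  lo <- strata$lo[idx]; hi <- strata$hi[idx]
  # starts may fall up to one element length before the stratum so that
  # per-base coverage stays uniform right up to interval boundaries;
  # clipping at the chromosome keeps coordinates valid
  starts <- round(stats::runif(k, lo - lens, hi))
  Lmap <- stats::setNames(anc_lengths$length, anc_lengths$anc_chrom)
  Lc <- unname(Lmap[as.character(strata$anc_chrom[idx])])
  out <- tibble(
    anc_chrom = strata$anc_chrom[idx],
    start = pmax(starts, 0),
    end = pmin(starts + lens, Lc)
  )
  out[out$end > out$start, , drop = FALSE]
}

# Keep a maximal prefix-greedy set of pairwise disjoint intervals.
greedy_disjoint <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x$anc_chrom, x$start, x$end), , drop = FALSE]
  keep <- logical(nrow(x))
  last_end <- -Inf; last_chr <- NA
  for (i in seq_len(nrow(x))) {
    if (!identical(x$anc_chrom[i], last_chr) || x$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- x$end[i]; last_chr <- x$anc_chrom[i]
    }
  }
  x[keep, , drop = FALSE]
}

#' Project element annotations into a genome's local coordinates
#'
#' Splits ancestral element intervals at segment boundaries and maps them
#' through the genome's segment list, honouring orientation.
#'
#' @param genome A `karyo_genome`.
#' @param scaffold_names Use emitted scaffold names.
#' @return Tibble: `chrom`, `start`, `end`, `class`, `family`, sorted.
#' @export
element_track <- function(genome, scaffold_names = TRUE) {
  el <- genome$anc_elements
  seg <- genome$segments
  if (nrow(el) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  class = character(), family = character()))
  }
  el <- dplyr::rename(el, el_start = start, el_end = end)
  j <- dplyr::inner_join(el, seg, by = "anc_chrom",
                         relationship = "many-to-many")
  j <- j[j$el_start < j$anc_end & j$el_end > j$anc_start, , drop = FALSE]
  mx <- pmax(j$el_start, j$anc_start) # element clipped to segment
  my <- pmin(j$el_end, j$anc_end)
  loc_s <- ifelse(j$strand == 1L,
                  j$start + (mx - j$anc_start),
                  j$start + (j$anc_end - my))
  loc_e <- ifelse(j$strand == 1L,
                  j$start + (my - j$anc_start),
                  j$start + (j$anc_end - mx))
  out <- tibble(
    chrom = if (scaffold_names) scaffold_name(genome, j$chrom) else j$chrom,
    start = loc_s, end = loc_e, class = j$class, family = j$family
  )
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Local junction coordinates of retained internal telomere remnants.
remnant_positions <- function(genome) {
  rem <- genome$remnants
  if (nrow(rem) == 0L) return(tibble(chrom = integer(), pos = double()))
  Lmap <- stats::setNames(genome$anc_lengths$length,
                          genome$anc_lengths$anc_chrom)
  seg <- genome$segments
  out <- purrr::pmap_dfr(rem, function(anc_chrom, side) {
    base <- if (side == "tail") Lmap[as.character(anc_chrom)] - 1 else 0
    s <- seg[seg$anc_chrom == anc_chrom &
               seg$anc_start <= base & seg$anc_end > base, , drop = FALSE]
    if (nrow(s) != 1L) return(tibble(chrom = integer(), pos = double()))
    off <- if (s$strand == 1L) base - s$anc_start else s$anc_end - base - 1
    l <- s$start + off
    pos <- if (l == s$end - 1) s$end else s$start
    tibble(chrom = s$chrom, pos = pos)
  })
  # Remnants mapping to an actual chromosome end are still terminal, not
  # internal; drop them.
  out <- dplyr::left_join(out, genome$chrom_lengths, by = "chrom")
  out <- out[out$pos > 0 & out$pos < out$length, c("chrom", "pos")]
  out
}

# Deterministic nucleotide sequence of one chromosome, with (TTAGG)n arrays
# written over flagged ends (CCTAA on the left end, i.e. the reverse
# complement strand) and over retained internal fusion remnants.
chromosome_sequence <- function(genome, chrom, config) {
  L <- genome$chrom_lengths$length[genome$chrom_lengths$chrom == chrom]
  if (length(L) != 1L) ks_abort("unknown chromosome", "input_error")
  arr_len <- 5L * config$telomere_array_copies
  bases <- withr::with_seed(
    (config$seed + seed_offset(genome$species, "seq", chrom)) %% .Machine$integer.max,
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  )
  telo <- genome$telomeres[genome$telomeres$chrom == chrom, , drop = FALSE]
  put <- function(bases, at, motif) {
    n <- ceiling(arr_len / 5)
    arr <- strsplit(strrep(motif, n), "")[[1]][seq_len(arr_len)]
    at <- max(0, min(at, L - arr_len))
    bases[(at + 1):(at + arr_len)] <- arr
    bases
  }
  if (nrow(telo) == 1L && arr_len > 0 && L >= arr_len) {
    if (telo$left) bases <- put(bases, 0, "CCTAA")
    if (telo$right) bases <- put(bases, L - arr_len, "TTAGG")
  }
  rp <- remnant_positions(genome)
  rp <- rp[rp$chrom == chrom, , drop = FALSE]
  if (nrow(rp) > 0 && arr_len > 0) {
    for (p in rp$pos) bases <- put(bases, round(p - arr_len / 2), "TTAGG")
  }
  paste(bases, collapse = "")
}
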