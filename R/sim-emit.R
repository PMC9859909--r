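# Emission of alignments, annotations and sequences from simulated genomes.

#' Emit pairwise alignment records between two simulated genomes
#'
#' Intersects the two genomes' segment maps in ancestral coordinates: every
#' homologous interval becomes a run of alignment pieces of roughly
#' `alignment_fragmentation_mean` bp with percent identity drawn in
#' (90, 100], oriented by the product of the segment orientations. Optional
#' singleton noise adds Poisson-distributed spurious short cross-chromosome
#' records (shorter than any plausible block threshold) per reference
#' chromosome.
#'
#' @param ref,query `karyo_genome`s derived from the same ancestral genome.
#' @param config The shared [sim_config()].
#' @return Tibble of alignment records: `ref`, `ref_start`, `ref_end`,
#'   `query`, `query_start`, `query_end`, `identity`, `strand`
#'   (0-based half-open, `start < end` on both sides).
#' @export
emit_alignments <- function(ref, query, config) {
  if (!isTRUE(all.equal(ref$anc_lengths, query$anc_lengths))) {
    ks_abort("ref and query do not derive from the same ancestral genome",
             "lineage_error")
  }
  withr::with_seed(
    (config$seed + 2L + seed_offset(ref$species, query$species)) %%
      .Machine$integer.max,
    {
      pieces <- homologous_pieces(ref, query)
      out <- chop_pieces(pieces, ref, query, config)
      noise <- noise_records(ref, query, config)
      res <- dplyr::bind_rows(out, noise)
      res[order(res$ref, res$ref_start), , drop = FALSE]
    }
  )
}

# Common refinement of the two segment partitions, in ancestral coordinates.
homologous_pieces <- function(ref, query) {
  rs <- ref$segments
  qs <- query$segments
  acc <- list()
  for (ac in unique(rs$anc_chrom)) {
    r <- rs[rs$anc_chrom == ac, , drop = FALSE]
    q <- qs[qs$anc_chrom == ac, , drop = FALSE]
    r <- r[order(r$anc_start), , drop = FALSE]
    q <- q[order(q$anc_start), , drop = FALSE]
    bounds <- sort(unique(c(r$anc_start, r$anc_end, q$anc_start, q$anc_end)))
    ps <- utils::head(bounds, -1L)
    pe <- bounds[-1L]
    ri <- findInterval(ps, r$anc_start)
    qi <- findInterval(ps, q$anc_start)
    acc[[length(acc) + 1L]] <- list(
      anc_chrom = rep(ac, length(ps)), anc_start = ps, anc_end = pe,
      r_chrom = r$chrom[ri], r_seg_start = r$start[ri],
      r_anc_start = r$anc_start[ri], r_anc_end = r$anc_end[ri],
      r_strand = r$strand[ri],
      q_chrom = q$chrom[qi], q_seg_start = q$start[qi],
      q_anc_start = q$anc_start[qi], q_anc_end = q$anc_end[qi],
      q_strand = q$strand[qi]
    )
  }
  cols <- names(acc[[1]])
  vals <- lapply(cols, function(cn) unlist(lapply(acc, `[[`, cn)))
  names(vals) <- cols
  tibble::new_tibble(vals, nrow = length(vals[[1]]))
}

chop_pieces <- function(pieces, ref, query, config) {
  if (nrow(pieces) == 0L) {
    return(tibble(ref = character(), ref_start = double(),
                  ref_end = double(), query = character(),
                  query_start = double(), query_end = double(),
                  identity = double(), strand = character()))
  }
  len <- pieces$anc_end - pieces$anc_start
  k <- pmax(1L, round(len / config$alignment_fragmentation_mean))
  idx <- rep(seq_len(nrow(pieces)), k)
  within <- sequence(k)
  p <- pieces[idx, , drop = FALSE]
  kk <- k[idx]
  plen <- len[idx]
  cs <- p$anc_start + round(plen * (within - 1) / kk)
  ce <- p$anc_start + round(plen * within / kk)
  keep <- ce > cs
  p <- p[keep, , drop = FALSE]; cs <- cs[keep]; ce <- ce[keep]
  r_s <- ifelse(p$r_strand == 1L,
                p$r_seg_start + (cs - p$r_anc_start),
                p$r_seg_start + (p$r_anc_end - ce))
  r_e <- ifelse(p$r_strand == 1L,
                p$r_seg_start + (ce - p$r_anc_start),
                p$r_seg_start + (p$r_anc_end - cs))
  q_s <- ifelse(p$q_strand == 1L,
                p$q_seg_start + (cs - p$q_anc_start),
                p$q_seg_start + (p$q_anc_end - ce))
  q_e <- ifelse(p$q_strand == 1L,
                p$q_seg_start + (ce - p$q_anc_start),
                p$q_seg_start + (p$q_anc_end - cs))
  tibble(
    ref = scaffold_name(ref, p$r_chrom),
    ref_start = r_s, ref_end = r_e,
    query = scaffold_name(query, p$q_chrom),
    query_start = q_s, query_end = q_e,
    identity = stats::runif(nrow(p), 90, 100),
    strand = ifelse(p$r_strand * p$q_strand == 1L, "+", "-")
  )
}

noise_records <- function(ref, query, config) {
  rate <- config$singleton_noise_rate
  if (rate <= 0) {
    return(NULL)
  }
  cl <- ref$chrom_lengths
  ql <- query$chrom_lengths
  n_per <- stats::rpois(nrow(cl), rate)
  total <- sum(n_per)
  if (total == 0L) return(NULL)
  rc <- rep(cl$chrom, n_per)
  rl <- rep(cl$length, n_per)
  w <- config$singleton_noise_len
  rs <- round(stats::runif(total, 0, pmax(rl - w, 1)))
  qc <- ql$chrom[sample.int(nrow(ql), total, replace = TRUE)]
  qlen <- ql$length[match(qc, ql$chrom)]
  qs <- round(stats::runif(total, 0, pmax(qlen - w, 1)))
  tibble(
    ref = scaffold_name(ref, rc), ref_start = rs, ref_end = rs + w,
    query = scaffold_name(query, qc), query_start = qs, query_end = qs + w,
    identity = stats::runif(total, 90, 100),
    strand = sample(c("+", "-"), total, replace = TRUE)
  )
}

#' Write a genome's annotations, sequences and length table to disk
#'
#' Produces a BED6 element annotation (0-based half-open, sorted; name field
#' `CLASS` or `LINE/family`), a FASTA with (TTAGG)n arrays written where
#' telomere flags are set (CCTAA on the left end; internal arrays at
#' retained fusion remnants), and a two-column chromosome length TSV.
#'
#' @param genome A `karyo_genome`.
#' @param config The [sim_config()] used to build it.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
emit_annotations_and_sequences <- function(genome, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- genome$species
  bed_path <- file.path(dir, paste0(sp, "_elements.bed"))
  fa_path <- file.path(dir, paste0(sp, ".fasta"))
  len_path <- file.path(dir, paste0(sp, "_lengths.tsv"))

  track <- element_track(genome)
  bed <- tibble(
    chrom = track$chrom, start = track$start, end = track$end,
    name = ifelse(is.na(track$family), track$class,
                  paste0(track$class, "/", track$family)),
    score = 0L, strand = "+"
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)

  seqs <- vapply(genome$chrom_lengths$chrom,
                 function(ch) chromosome_sequence(genome, ch, config),
                 character(1))
  names(seqs) <- scaffold_name(genome, genome$chrom_lengths$chrom)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa_path)

  readr::write_tsv(chromosome_lengths(genome), len_path)
  c(elements = bed_path, fasta = fa_path, lengths = len_path)
}

#' Read a BED element annotation back into a track tibble
#'
#' @param path BED file whose name column is `CLASS` or `CLASS/family`.
#' @return Tibble: `chrom`, `start`, `end`, `class`, `family`.
#' @export
read_elements <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  parts <- stringr::str_split_fixed(bed$name, stringr::fixed("/"), 2)
  tibble(
    chrom = bed$chrom, start = as.numeric(bed$start),
    end = as.numeric(bed$end),
    class = parts[, 1],
    family = ifelse(parts[, 2] == "", NA_character_, parts[, 2])
  )
}

#' Write / read a ground-truth event log
#'
#' @param log Log tibble from a `karyo_sim`.
#' @param path TSV path.
#' @return `write_ground_truth()` the path, invisibly; `read_ground_truth()`
#'   the log tibble.
#' @export
write_ground_truth <- function(log, path) {
  readr::write_tsv(log, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    branch = "c", step = "i", type = "c", chrom_a = "i", chrom_b = "i",
    pos_a = "d", pos_b = "d", pos_c = "d", end_a = "c", end_b = "c",
    retain = "l", anc_chrom_a = "i", anc_pos_a = "d",
    anc_chrom_b = "i", anc_pos_b = "d"
  ), progress = FALSE)
}
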