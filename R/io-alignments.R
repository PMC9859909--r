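# Readers and writers for pairwise alignment coordinate files.
#
# Two dialects:
#   coords — the tab output of nucmer's show-coords (-T): columns
#            S1 E1 S2 E2 LEN1 LEN2 %IDY REF QUERY, 1-based inclusive;
#            a minus-strand alignment has its query coordinates reversed.
#   paf    — minimal PAF columns 1-12 (0-based half-open, explicit strand);
#            identity is reconstructed as 100 * matches / block length.
# Internally everything is 0-based half-open with start < end on both sides.

aln_cols <- c("ref", "ref_start", "ref_end", "query", "query_start",
              "query_end", "identity", "strand")

#' Read pairwise alignment coordinates
#'
#' @param path File path.
#' @param dialect `"coords"` (nucmer show-coords tab output) or `"paf"`.
#' @return Tibble of alignment records with 0-based half-open coordinates,
#'   `start < end` on both sides, `identity` in \[0, 100\] and `strand`
#'   inferred from coordinate order (coords) or the strand column (PAF).
#' @examples
#' aln <- tibble::tibble(
#'   ref = "r1", ref_start = 0, ref_end = 1000, query = "q1",
#'   query_start = 0, query_end = 1000, identity = 95, strand = "+"
#' )
#' f <- tempfile(fileext = ".paf")
#' write_alignments(aln, f, dialect = "paf")
#' read_alignments(f, dialect = "paf")
#' @export
read_alignments <- function(path, dialect = c("coords", "paf")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) ks_abort(
                        "dialect must be 'coords' or 'paf'", "usage_error"))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(ref = character(), ref_start = double(),
                  ref_end = double(), query = character(),
                  query_start = double(), query_end = double(),
                  identity = double(), strand = character()))
  }
  fields <- stringr::str_split(lines, "\t")
  n_min <- if (dialect == "coords") 9L else 12L
  bad <- which(lengths(fields) < n_min)
  if (length(bad) > 0L) {
    ks_abort(paste0("malformed ", dialect, " line ", bad[1], " in ", path),
             "parse_error")
  }
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(n_min)]))
  if (dialect == "coords") {
    num <- suppressWarnings(apply(m[, 1:7, drop = FALSE], 2, as.numeric))
    num <- matrix(num, ncol = 7)
    if (anyNA(num)) {
      ks_abort(paste0("malformed coords line ",
                      which(rowSums(is.na(num)) > 0)[1], " in ", path),
               "parse_error")
    }
    s1 <- num[, 1]; e1 <- num[, 2]; s2 <- num[, 3]; e2 <- num[, 4]
    out <- tibble(
      ref = m[, 8], ref_start = pmin(s1, e1) - 1, ref_end = pmax(s1, e1),
      query = m[, 9], query_start = pmin(s2, e2) - 1,
      query_end = pmax(s2, e2),
      identity = num[, 7],
      strand = ifelse(s2 <= e2, "+", "-")
    )
  } else {
    num_idx <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
    num <- suppressWarnings(apply(m[, num_idx, drop = FALSE], 2, as.numeric))
    num <- matrix(num, ncol = length(num_idx))
    if (anyNA(num)) {
      ks_abort(paste0("malformed PAF line ",
                      which(rowSums(is.na(num)) > 0)[1], " in ", path),
               "parse_error")
    }
    out <- tibble(
      ref = m[, 6], ref_start = num[, 5], ref_end = num[, 6],
      query = m[, 1], query_start = num[, 2], query_end = num[, 3],
      identity = 100 * num[, 7] / num[, 8],
      strand = m[, 5]
    )
  }
  if (any(out$ref_start >= out$ref_end) ||
      any(out$query_start >= out$query_end)) {
    ks_abort(paste0("zero-length alignment in ", path), "parse_error")
  }
  out
}

#' Write pairwise alignment coordinates
#'
#' @param alignments Alignment tibble (as produced by [emit_alignments()]
#'   or [read_alignments()]).
#' @param path Output path.
#' @param dialect `"coords"` or `"paf"`.
#' @param ref_lengths,query_lengths Optional scaffold length tibbles
#'   (`chrom`, `length`); PAF requires total lengths, which otherwise fall
#'   back to the maximum end coordinate seen per scaffold.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path,
                             dialect = c("coords", "paf"),
                             ref_lengths = NULL, query_lengths = NULL) {
  dialect <- match.arg(dialect)
  a <- alignments
  assert_cols(a, aln_cols, "alignments")
  if (dialect == "coords") {
    minus <- a$strand == "-"
    out <- data.frame(
      s1 = a$ref_start + 1, e1 = a$ref_end,
      s2 = ifelse(minus, a$query_end, a$query_start + 1),
      e2 = ifelse(minus, a$query_start + 1, a$query_end),
      len1 = a$ref_end - a$ref_start,
      len2 = a$query_end - a$query_start,
      idy = formatC(a$identity, format = "f", digits = 4),
      ref = a$ref, query = a$query
    )
    readr::write_tsv(out, path, col_names = FALSE)
  } else {
    len_of <- function(tbl, nms, ends) {
      if (!is.null(tbl)) {
        stats::setNames(tbl$length, tbl$chrom)[nms]
      } else {
        stats::ave(ends, nms, FUN = max)
      }
    }
    alen <- pmax(a$ref_end - a$ref_start, a$query_end - a$query_start)
    out <- data.frame(
      qname = a$query,
      qlen = len_of(query_lengths, a$query, a$query_end),
      qstart = a$query_start, qend = a$query_end,
      strand = a$strand,
      tname = a$ref,
      tlen = len_of(ref_lengths, a$ref, a$ref_end),
      tstart = a$ref_start, tend = a$ref_end,
      nmatch = round(a$identity / 100 * alen),
      alen = alen,
      mapq = 60L
    )
    readr::write_tsv(out, path, col_names = FALSE)
  }
  invisible(path)
}

#' Read a chromosome length table
#'
#' Accepts a two-column TSV (`chrom`, `length`), with or without a header,
#' or the first two columns of a samtools `.fai` index.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `length`.
#' @export
read_lengths <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- !grepl("\t[0-9]+(\t|$)", first)
  tab <- readr::read_tsv(path, col_names = has_header, progress = FALSE,
                         col_types = readr::cols())
  tibble(chrom = as.character(tab[[1]]), length = as.numeric(tab[[2]]))
}
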