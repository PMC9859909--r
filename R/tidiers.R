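# tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a randomization test
#'
#' @param x A `karyo_randtest`.
#' @param ... Unused.
#' @return One row per distinct null overlap count with its frequency.
#' @method tidy karyo_randtest
#' @export
tidy.karyo_randtest <- function(x, ...) {
  tab <- table(x$null_counts)
  tibble(null_overlap = as.integer(names(tab)),
         n = as.integer(tab),
         proportion = as.integer(tab) / x$n_iter)
}

#' @rdname tidy.karyo_randtest
#' @return `glance()`: one row with `observed`, `p`, `n_iter`,
#'   `null_mean`.
#' @method glance karyo_randtest
#' @export
glance.karyo_randtest <- function(x, ...) {
  tibble(observed = x$observed, p = x$p, n_iter = x$n_iter,
         null_mean = mean(x$null_counts))
}

#' Tidy an enrichment result
#'
#' @param x A `karyo_enrichment`.
#' @param ... Unused.
#' @return One-row tibble with class, observed and null densities, sd,
#'   two-tailed p and direction.
#' @method tidy karyo_enrichment
#' @export
tidy.karyo_enrichment <- function(x, ...) {
  tibble(class = x$class, n_windows = x$n_windows, observed = x$observed,
         null_mean = x$null_mean, null_sd = x$null_sd, p = x$p,
         direction = x$direction)
}

#' @rdname tidy.karyo_enrichment
#' @method glance karyo_enrichment
#' @export
glance.karyo_enrichment <- function(x, ...) tidy(x)

#' Tidy polarized event calls
#'
#' @param x A `karyo_polarized`.
#' @param ... Unused.
#' @return `tidy()`: the per-event table with final type, branch and rule;
#'   `glance()`: one row with totals and the clade fusion fraction (%).
#' @method tidy karyo_polarized
#' @export
tidy.karyo_polarized <- function(x, ...) {
  ev <- x$events
  ev$shared_by <- vapply(ev$shared_by, paste, character(1), collapse = ",")
  tibble::as_tibble(ev)
}

#' @rdname tidy.karyo_polarized
#' @method glance karyo_polarized
#' @export
glance.karyo_polarized <- function(x, ...) {
  tibble(n_events = nrow(x$events), n_considered = x$n_total,
         n_overlap = x$n_overlap, fusion_fraction = x$fusion_fraction)
}

#' Tidy a telomeric LINE screen
#'
#' @param x A `karyo_telo_screen`.
#' @param ... Unused.
#' @return `tidy()`: the per-family table; `glance()`: totals and the
#'   flagged-family fraction of LINE bp in fusion windows.
#' @method tidy karyo_telo_screen
#' @export
tidy.karyo_telo_screen <- function(x, ...) x$families

#' @rdname tidy.karyo_telo_screen
#' @method glance karyo_telo_screen
#' @export
glance.karyo_telo_screen <- function(x, ...) {
  tibble(n_families = nrow(x$families), n_flagged = length(x$flagged),
         flagged_fraction = x$fraction)
}

#' Tidy a recovery result
#'
#' @param x A `karyo_recovery`.
#' @param ... Unused.
#' @return The per-branch fission/fusion count table.
#' @method tidy karyo_recovery
#' @export
tidy.karyo_recovery <- function(x, ...) x$counts
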