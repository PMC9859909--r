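# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom dplyr filter mutate select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of desc distinct pull rename
#' @importFrom tibble tibble as_tibble
NULL

# Consistent error with a class so tests can assert on condition classes.
ks_abort <- function(msg, class) {
  abort(msg, class = c(class, "karyoshift_error"))
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    ks_abort(
      paste0(what, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      "input_error"
    )
  }
  invisible(df)
}

# Deterministic small integer derived from strings, for per-pair RNG streams.
# Kept well below 2^31 so seed arithmetic stays in integer range.
seed_offset <- function(...) {
  s <- paste(..., collapse = "|")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97L + 1L)) %% 1000003L
}

`%needs%` <- function(x, cls) inherits(x, cls)
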