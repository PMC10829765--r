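# Frequency spectrum construction, novelty scoring and quartile-based
# selection of trends (weak signals) and tentative wild cards.
#
# The novelty of a design solution with frequency C among T detected signals
# is S = (T - C)/T * 10: a solution carried by every signal scores 0, a
# unique one approaches 10. T is the number of selected signals, not the
# number of distinct DSCs; a multifunctional signal increments each of its
# DSCs' counts but counts once toward T.

#' Round half-up
#'
#' Deterministic half-up rounding for display values (base `round()` rounds
#' half to even). Scores are kept at full precision internally; only printed
#' values are rounded.
#'
#' @param x Numeric vector (non-negative in this package's use).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Build a design-solution frequency spectrum
#'
#' Each selected signal contributes one count to each of its DSCs; the
#' spectrum total `T` is the number of selected signals. Entries are ordered
#' by descending count, ties broken by DSC string ascending so the ordering
#' (and hence quartile selection) is deterministic.
#'
#' @param db A `signal_db` with at least one selected signal.
#' @return A `dsc_spectrum`: a tibble with columns `dsc` and `count` and
#'   attribute `total`.
#' @export
build_spectrum <- function(db) {
  stopifnot(inherits(db, "signal_db"))
  long <- signal_dsc_long(db)
  n_selected <- sum(db$signals$status == "selected")
  if (n_selected == 0L) stop("no selected signals; cannot build a spectrum",
                             call. = FALSE)
  counts <- table(long$dsc)
  new_spectrum(tibble::tibble(dsc = names(counts), count = as.integer(counts)),
               total = n_selected)
}

#' Construct a spectrum from explicit counts
#'
#' Mainly for analyses and tests that start from a known frequency vector
#' rather than a signal database.
#'
#' @param entries Tibble or data frame with columns `dsc` and `count`
#'   (positive integers), or a named integer vector.
#' @param total The spectrum total `T` (number of detected signals). Defaults
#'   to `sum(count)`, which is exact when every signal carries one DSC.
#' @return A `dsc_spectrum`.
#' @export
new_spectrum <- function(entries, total = NULL) {
  if (!is.data.frame(entries))
    entries <- tibble::tibble(dsc = names(entries), count = as.integer(entries))
  entries <- tibble::as_tibble(entries[, c("dsc", "count")])
  entries$count <- as.integer(entries$count)
  if (any(entries$count < 1L)) stop("spectrum counts must be positive", call. = FALSE)
  if (anyDuplicated(entries$dsc)) stop("duplicated DSC in spectrum", call. = FALSE)
  if (is.null(total)) total <- sum(entries$count)
  total <- as.integer(total)
  if (total < 1L) stop("spectrum total must be positive", call. = FALSE)
  entries <- entries[order(-entries$count, entries$dsc), ]
  structure(entries, total = total, class = c("dsc_spectrum", class(entries)))
}

#' @export
print.dsc_spectrum <- function(x, ...) {
  cat("<dsc_spectrum> ", nrow(x), " design solutions over T = ",
      attr(x, "total"), " detected signals\n", sep = "")
  NextMethod()
}

#' Novelty score of a design solution
#'
#' `S = (T - C) / T * 10`, where `C` is the design solution's frequency and
#' `T` the total number of detected signals. Strictly decreasing in `C`:
#' `S = 0` when every signal carries the solution, and approaches (never
#' reaches) 10 as the solution becomes unique. Returned at full precision;
#' use [round_half_up()] for the conventional 2-decimal display.
#'
#' @param C Frequency (vector of positive integers, each `<= T`).
#' @param T_total Total number of detected signals (positive).
#' @return Numeric vector of scores in `[0, 10)`.
#' @examples
#' round_half_up(novelty_score(95, 836), 2) # 8.86
#' @export
novelty_score <- function(C, T_total) {
  if (length(T_total) != 1L || is.na(T_total) || T_total < 1)
    stop("T must be a single positive integer", call. = FALSE)
  if (any(is.na(C)) || any(C < 1) || any(C > T_total))
    stop("C must satisfy 1 <= C <= T", call. = FALSE)
  (T_total - C) / T_total * 10
}

#' Cumulative novelty table
#'
#' Orders design solutions by descending frequency (ascending novelty) and
#' accumulates counts, giving the cumulative-percentage representation on
#' which the quartile thresholds are read.
#'
#' @param spectrum A `dsc_spectrum`.
#' @return A tibble with columns `dsc`, `count`, `score`, `cum_count` and
#'   `cum_percent` (of the total count mass; non-decreasing, ending at 100).
#' @export
cumulative_table <- function(spectrum) {
  stopifnot(inherits(spectrum, "dsc_spectrum"))
  total <- attr(spectrum, "total")
  tibble::tibble(
    dsc = spectrum$dsc,
    count = spectrum$count,
    score = novelty_score(spectrum$count, total),
    cum_count = cumsum(spectrum$count),
    cum_percent = cumsum(spectrum$count) / sum(spectrum$count) * 100
  )
}

#' Select trends (weak signals) at the first quartile
#'
#' Walking the spectrum in descending-frequency order, a design solution is
#' a trend iff the cumulative count before it is below `q1_fraction * T`:
#' the high-frequency head of the distribution up to and including the DSC
#' whose interval crosses the Q1 mark.
#'
#' @param spectrum A `dsc_spectrum`.
#' @param q1_fraction First-quartile fraction of `T` (default 0.25).
#' @return A list with `dscs` (trend DSC strings, in spectrum order),
#'   `signal_count` (summed counts of the trend DSCs, i.e. the signals they
#'   represent) and `table` (the trend rows of the cumulative table).
#' @export
select_weak_signals <- function(spectrum, q1_fraction = 0.25) {
  ct <- cumulative_table(spectrum)
  total <- attr(spectrum, "total")
  before <- ct$cum_count - ct$count
  keep <- before < q1_fraction * total
  list(dscs = ct$dsc[keep],
       signal_count = sum(ct$count[keep]),
       table = ct[keep, ])
}

#' Select tentative wild cards at the third quartile
#'
#' Mirror rule to [select_weak_signals()]: a design solution is a tentative
#' wild card iff the cumulative count through it exceeds `q3_fraction * T` —
#' its interval crosses or lies beyond the Q3 mark in the low-frequency tail.
#' On degenerate spectra whose Q1 and Q3 crossings coincide, DSCs already
#' selected as trends are dropped from the wild-card set with a warning.
#'
#' @param spectrum A `dsc_spectrum`.
#' @param q3_fraction Third-quartile fraction of `T` (default 0.75).
#' @param q1_fraction Used only to detect trend/wild-card overlap.
#' @return A list with `dscs`, `table` (tail rows of the cumulative table)
#'   and `degenerate` (`TRUE` when the tail intersected the trend head).
#' @export
select_tentative_wildcards <- function(spectrum, q3_fraction = 0.75,
                                       q1_fraction = 0.25) {
  ct <- cumulative_table(spectrum)
  total <- attr(spectrum, "total")
  keep <- ct$cum_count > q3_fraction * total
  trends <- select_weak_signals(spectrum, q1_fraction)$dscs
  overlap <- intersect(ct$dsc[keep], trends)
  degenerate <- length(overlap) > 0L
  if (degenerate) {
    warning("degenerate spectrum: ", length(overlap),
            " DSC(s) fall in both the trend head and the wild-card tail; ",
            "dropped from the wild-card set", call. = FALSE)
    keep <- keep & !ct$dsc %in% trends
  }
  list(dscs = ct$dsc[keep], table = ct[keep, ], degenerate = degenerate)
}

#' Combined quartile selection
#'
#' Runs [select_weak_signals()] and [select_tentative_wildcards()] on one
#' spectrum and, given the database, resolves the tentative wild-card signal
#' set: selected signals carrying at least one wild-card DSC and no trend
#' DSC.
#'
#' @param spectrum A `dsc_spectrum`.
#' @param db Optional `signal_db`; when supplied the signal-level wild-card
#'   set is computed.
#' @param q1_fraction,q3_fraction Quartile fractions of `T`.
#' @return An object of class `quartile_selection`: list with `trends`,
#'   `trend_signal_count`, `wildcard_dscs`, `degenerate`,
#'   `wildcard_signal_ids` (when `db` given) and the two selection tables.
#' @export
quartile_selection <- function(spectrum, db = NULL, q1_fraction = 0.25,
                               q3_fraction = 0.75) {
  ws <- select_weak_signals(spectrum, q1_fraction)
  wc <- select_tentative_wildcards(spectrum, q3_fraction, q1_fraction)
  out <- list(trends = ws$dscs,
              trend_signal_count = ws$signal_count,
              trend_table = ws$table,
              wildcard_dscs = wc$dscs,
              wildcard_table = wc$table,
              degenerate = wc$degenerate,
              q1_fraction = q1_fraction,
              q3_fraction = q3_fraction,
              wildcard_signal_ids = NULL)
  if (!is.null(db)) out$wildcard_signal_ids <- tentative_wildcard_signals(db, out)
  structure(out, class = "quartile_selection")
}

#' @export
print.quartile_selection <- function(x, ...) {
  cat("<quartile_selection> ", length(x$trends), " trend DSC(s) covering ",
      x$trend_signal_count, " signals; ", length(x$wildcard_dscs),
      " tentative wild-card DSC(s)", if (x$degenerate) " [degenerate]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Tentative wild-card signals
#'
#' The signal-level counterpart of the Q3 tail: selected signals that carry
#' at least one tentative wild-card DSC and no trend DSC.
#'
#' @param db A `signal_db`.
#' @param selection A `quartile_selection` (or list with `trends` and
#'   `wildcard_dscs`).
#' @return Character vector of signal ids.
#' @export
tentative_wildcard_signals <- function(db, selection) {
  long <- signal_dsc_long(db)
  has_wc <- unique(long$signal_id[long$dsc %in% selection$wildcard_dscs])
  has_trend <- unique(long$signal_id[long$dsc %in% selection$trends])
  setdiff(has_wc, has_trend)
}
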