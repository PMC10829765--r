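# Synthetic signal databases and regulatory tables with the statistical
# structure the analysis assumes: a top-heavy DSC frequency spectrum (three
# planted high-frequency trends over a Zipf-like, singleton-rich tail),
# three source strata with realistic selected/discarded tallies, and a
# handful of planted multifunctional triple-DSC wild cards whose DSC
# combinations are unique.

# Default per-(source, period) scan tallies: nine strata, 836 selected and
# 558 discarded signals overall (102 / 524 / 210 selected per source).
default_strata <- function() {
  tibble::tibble(
    source = rep(c("scopus", "epo", "clinicaltrials"), each = 3),
    scan_period = rep(c("1", "2", "3"), times = 3),
    selected = c(57L, 25L, 20L, 309L, 99L, 116L, 193L, 9L, 8L),
    not_selected = c(169L, 32L, 27L, 86L, 27L, 22L, 166L, 14L, 15L)
  )
}

# Largest-remainder scaling of integer count vectors to a new total.
scale_counts <- function(counts, new_total) {
  if (sum(counts) == 0L) return(counts)
  raw <- counts / sum(counts) * new_total
  out <- floor(raw)
  rem <- new_total - sum(out)
  if (rem > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  as.integer(out)
}

default_planted_trends <- function() {
  tibble::tibble(dsc = c("B.T.2.3", "E.T.2.1", "C.T.2.3"),
                 count = c(95L, 61L, 61L))
}

# Five planted multifunctional wild cards: triple-DSC combinations with
# pairwise-disjoint DSC sets (every planted DSC has frequency 1, placing all
# of them in the singleton tail), signatures with exactly one multivalued
# position, no DSC shared with the planted trends, no unspecific code.
# Synthesized filler codes use the reserved "X*" solution-id prefix.
default_planted_wildcards <- function() {
  tibble::tibble(
    dscs = c("F.T.2.1;A.T.2.2;P.T.2.3",
             "K.T.1.1;XA.T.2.1;E.T.2.2",
             "B.T.1.1;G.T.2.1;L.T.2.3",
             "XB.T.1.1;H.T.1.1;XC.T.2.1",
             "R.T.2.1;B.T.2.2;XD.T.2.3"),
    signature = c("2.(1.2.3).1.1", "1.1.(2.3).1", "1.1.(1.2).1",
                  "(1.2).1.1.1", "2.(1.2.3).1.1")
  )
}

#' Generator configuration
#'
#' Assembles and validates the parameters of the synthetic signal-database
#' generator. The defaults reproduce the study conditions: 836 selected
#' signals split 102/524/210 across literature, patent and clinical-trial
#' strata over three scan periods (plus 558 discarded records so scan
#' tallies are realistic), three planted trend DSCs with counts 95/61/61, a
#' Zipf-like tail (largest tail count 45) with a singleton floor, and five
#' planted triple-DSC multifunctional wild cards with unique combinations.
#'
#' @param n_signals Number of selected signals (`T`).
#' @param strata Tibble with `source`, `scan_period`, `selected`,
#'   `not_selected`; scaled by largest remainder when `n_signals` differs
#'   from its selected total.
#' @param planted_trends Tibble with `dsc`, `count`: high-frequency DSCs
#'   planted with exactly these counts.
#' @param planted_wildcards Tibble with `dscs` (semicolon-joined triples)
#'   and `signature` (one multivalued position); their combinations are
#'   unique by construction.
#' @param tail_exponent Zipf-like decay exponent of the non-singleton tail.
#' @param singleton_fraction Fraction of tail signals assigned to
#'   frequency-1 DSCs (the singleton floor).
#' @param tail_max_count Largest tail DSC count; must stay below the
#'   smallest planted trend count.
#' @param unspecific_rate Probability that a tail signal carries an
#'   additional unspecific (Y/Z) DSC.
#' @param include_discarded Emit discarded rows per the strata table.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_signals = 836,
                             strata = default_strata(),
                             planted_trends = default_planted_trends(),
                             planted_wildcards = default_planted_wildcards(),
                             tail_exponent = 1.6,
                             singleton_fraction = 0.30,
                             tail_max_count = 45,
                             unspecific_rate = 0.02,
                             include_discarded = TRUE,
                             seed = 1L) {
  n_signals <- as.integer(n_signals)
  if (n_signals < 1L) stop("n_signals must be positive", call. = FALSE)
  if (singleton_fraction < 0 || singleton_fraction > 1)
    stop("singleton_fraction must be in [0, 1]", call. = FALSE)
  if (unspecific_rate < 0 || unspecific_rate > 1)
    stop("unspecific_rate must be in [0, 1]", call. = FALSE)
  planted_trends <- tibble::as_tibble(planted_trends)
  planted_wildcards <- tibble::as_tibble(planted_wildcards)
  planted_mass <- sum(planted_trends$count) + nrow(planted_wildcards)
  if (planted_mass > n_signals)
    stop("infeasible config: planted trend counts (", sum(planted_trends$count),
         ") plus planted wild cards (", nrow(planted_wildcards),
         ") exceed n_signals (", n_signals, ")", call. = FALSE)
  if (nrow(planted_trends) &&
      any(planted_trends$count <= tail_max_count) &&
      n_signals - planted_mass > 0)
    warning("some planted trend counts do not exceed tail_max_count; ",
            "the planted head may not dominate the spectrum", call. = FALSE)
  strata <- tibble::as_tibble(strata)
  if (sum(strata$selected) != n_signals) {
    strata$selected <- scale_counts(strata$selected, n_signals)
    strata$not_selected <- scale_counts(strata$not_selected,
                                        round(sum(strata$not_selected) *
                                              n_signals / 836))
  }
  structure(list(n_signals = n_signals, strata = strata,
                 planted_trends = planted_trends,
                 planted_wildcards = planted_wildcards,
                 tail_exponent = tail_exponent,
                 singleton_fraction = singleton_fraction,
                 tail_max_count = tail_max_count,
                 unspecific_rate = unspecific_rate,
                 include_discarded = include_discarded,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic Zipf-like tail: counts max_count * k^-exponent (floored at
# 2) until the non-singleton mass is spent; the remainder (plus the
# singleton floor) becomes frequency-1 DSCs.
tail_count_sequence <- function(n_tail, exponent, singleton_fraction, max_count) {
  if (n_tail <= 0L) return(integer())
  n_singletons <- round(singleton_fraction * n_tail)
  mass <- n_tail - n_singletons
  counts <- integer()
  k <- 1
  while (mass >= 2L) {
    ck <- min(mass, max(2L, as.integer(round(max_count * k^(-exponent)))))
    counts <- c(counts, ck)
    mass <- mass - ck
    k <- k + 1
  }
  n_singletons <- n_singletons + mass
  c(counts, rep(1L, n_singletons))
}

# Tail DSC alphabet: two-letter solution ids, skipping the reserved
# unspecific letters and the "X*" prefix kept for planted wild cards.
tail_dsc_ids <- function(n) {
  first <- setdiff(LETTERS, c("X", "Y", "Z"))
  ids <- as.vector(outer(first, LETTERS, paste0))
  if (n > length(ids)) stop("tail alphabet exhausted", call. = FALSE)
  ids[seq_len(n)]
}

# Signature pools for the planted trends, echoing the dominant families
# observed for each: polymeric carriers mostly "2.3.2.1", lipid carriers
# mostly self-assembling carbon-based "2.3.3s.1", dental materials a varied
# "2.1.x.y" family.
trend_signature <- function(dsc, n) {
  switch(dsc,
    "B.T.2.3" = sample(c("2.3.2.1", "2.3.2.2", "2.3.1.1", "2.3.3.1"), n,
                       replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    "E.T.2.1" = paste("2.1",
                      sample(c("1", "2", "3", "0"), n, replace = TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)),
                      sample(c("0", "1", "2"), n, replace = TRUE,
                             prob = c(0.5, 0.3, 0.2)), sep = "."),
    "C.T.2.3" = sample(c("2.3.3s.1", "2.3.3.1", "2.3.2.1"), n,
                       replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    # non-default planted trend: derive from the DSC's own mode/purpose
    paste(as_dsc(dsc)$mode_of_action, as_dsc(dsc)$medical_purpose,
          sample(c("0", "1", "2", "3", "3s"), n, replace = TRUE),
          sample(c("0", "1", "2"), n, replace = TRUE), sep = ".")
  )
}

#' Generate a synthetic signal database
#'
#' Deterministic given the seed. The planted trend DSCs appear with exactly
#' their configured counts; planted wild cards keep unique DSC combinations
#' sharing nothing with the trends; tail DSCs follow the configured
#' Zipf-like law with a singleton floor placed entirely beyond the Q3 mark
#' of the cumulative count axis; source/period strata hold exact counts.
#'
#' @param config A [generator_config()].
#' @return A `signal_db`.
#' @examples
#' db <- generate_signals(generator_config(seed = 1))
#' print(db)
#' @export
generate_signals <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  trends <- config$planted_trends
  wcs <- config$planted_wildcards
  n_trend <- sum(trends$count)
  n_wc <- nrow(wcs)
  n_tail <- config$n_signals - n_trend - n_wc

  # trend signals: one DSC each, signature drawn from the trend's family
  trend_dsc <- rep(trends$dsc, trends$count)
  trend_sig <- unlist(lapply(seq_len(nrow(trends)), function(i)
    trend_signature(trends$dsc[i], trends$count[i])))

  # tail signals: one DSC each from the Zipf-like law, plus an optional
  # unspecific extra code
  tail_counts <- tail_count_sequence(n_tail, config$tail_exponent,
                                     config$singleton_fraction,
                                     config$tail_max_count)
  if (length(tail_counts) == 0L) {
    tail_dscs_col <- character(0)
    tail_sig <- character(0)
  } else {
  ids <- tail_dsc_ids(length(tail_counts))
  tail_mode <- sample(c("1", "2"), length(tail_counts), replace = TRUE,
                      prob = c(0.35, 0.65))
  tail_purpose <- sample(c("1", "2", "3"), length(tail_counts), replace = TRUE,
                         prob = c(0.45, 0.30, 0.25))
  tail_dsc_str <- paste(ids, "T", tail_mode, tail_purpose, sep = ".")
  tail_dsc <- rep(tail_dsc_str, tail_counts)
  tail_mode_rep <- rep(tail_mode, tail_counts)
  tail_purpose_rep <- rep(tail_purpose, tail_counts)
  tail_sig <- paste(tail_mode_rep, tail_purpose_rep,
                    sample(c("0", "1", "2", "3", "1s", "2s", "3s"),
                           length(tail_dsc), replace = TRUE,
                           prob = c(0.15, 0.2, 0.25, 0.2, 0.05, 0.08, 0.07)),
                    sample(c("0", "1", "2"), length(tail_dsc), replace = TRUE,
                           prob = c(0.3, 0.5, 0.2)), sep = ".")
  extra <- stats::runif(length(tail_dsc)) < config$unspecific_rate
  unspec <- paste(sample(c("Y", "Z"), length(tail_dsc), replace = TRUE),
                  "T", tail_mode_rep, tail_purpose_rep, sep = ".")
  tail_dscs_col <- ifelse(extra, paste(tail_dsc, unspec, sep = ";"), tail_dsc)
  }

  sel <- tibble::tibble(
    dscs = c(trend_dsc, tail_dscs_col, wcs$dscs),
    signature = c(trend_sig, tail_sig, wcs$signature)
  )
  # exact per-stratum source/period counts, randomly assigned to signals
  strata <- config$strata
  slot <- sample(rep(seq_len(nrow(strata)), strata$selected))
  sel$source <- strata$source[slot]
  sel$scan_period <- strata$scan_period[slot]
  sel$status <- "selected"
  sel$discard_reason <- ""

  if (config$include_discarded && sum(strata$not_selected) > 0) {
    reasons <- c("not describing an NHP in particular",
                 "source document not available",
                 "outside the selected timeframe",
                 "duplicated record",
                 "not at the nano-scale")
    nd <- sum(strata$not_selected)
    dslot <- rep(seq_len(nrow(strata)), strata$not_selected)
    disc <- tibble::tibble(
      dscs = "", signature = "",
      source = strata$source[dslot],
      scan_period = strata$scan_period[dslot],
      status = "discarded",
      discard_reason = sample(reasons, nd, replace = TRUE,
                              prob = c(0.6, 0.15, 0.1, 0.05, 0.1)))
    all_rows <- dplyr::bind_rows(sel, disc)
  } else {
    all_rows <- sel
  }

  all_rows$signal_id <- sprintf("SIG%05d", seq_len(nrow(all_rows)))
  all_rows$source_ref <- ""
  signal_db(all_rows[signal_columns],
            provenance = c("synthetic horizon-scanning signal database",
                           paste0("generator seed ", config$seed),
                           paste0("n_signals ", config$n_signals)))
}

#' Generate a regulatory-document table
#'
#' Returns the packaged nine-document table of galenic-NHP guidance,
#' optionally augmented with randomly generated documents whose patterns are
#' drawn over the signature-pattern alphabet (all parse under the pattern
#' grammar).
#'
#' @param n_extra Number of synthetic documents to append.
#' @param seed Seed for the synthetic rows (only used when `n_extra > 0`).
#' @return A regulatory-document tibble (`source`, `status`, `name`,
#'   `nhp_pattern`).
#' @export
generate_regdb <- function(n_extra = 0, seed = 1L) {
  base <- read_regdb()
  if (n_extra <= 0) return(base)
  set.seed(as.integer(seed))
  pos <- function(alphabet, n)
    sample(c(alphabet, "n"), n, replace = TRUE)
  pats <- paste(pos(c("1", "2"), n_extra), pos(c("1", "2", "3"), n_extra),
                pos(c("0", "1", "2", "3", "3s"), n_extra),
                pos(c("0", "1", "2"), n_extra), sep = ".")
  extra <- tibble::tibble(
    source = sample(regdb_sources, n_extra, replace = TRUE),
    status = "Synthetic",
    name = sprintf("Synthetic regulatory document %03d", seq_len(n_extra)),
    nhp_pattern = pats)
  dplyr::bind_rows(base, extra)
}
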