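# Correction-factor enrichment of tentative wild cards.
#
# Near the tail of the spectrum almost every DSC combination is unique, so
# raw novelty scores bunch just below 10 and cannot rank candidates. Four
# correction criteria re-weight them:
#   Z - an unspecific (Y/Z) DSC annihilates the score (factor 0 vs 1);
#   N - multifunctionality is enriched (1 DSC -> 1, 2 -> 3/2, >2 -> 2);
#   S - sharing DSCs with trends is penalised (0 shared -> 2, 1 -> 2/3,
#       >1 -> 1/2);
#   C - sharing a trend NHP signature is penalised (yes -> 1, no -> 2).
# The combined factor is the product of the four; a signal's corrected score
# is its raw combination novelty times that factor, and zero-factor signals
# are removed before ranking.

criterion_z_factor <- function(has_unspecific) ifelse(has_unspecific, 0, 1)

criterion_n_factor <- function(n_dscs) {
  stopifnot(all(n_dscs >= 1L))
  ifelse(n_dscs == 1L, 1, ifelse(n_dscs == 2L, 3 / 2, 2))
}

criterion_s_factor <- function(n_shared) {
  stopifnot(all(n_shared >= 0L))
  ifelse(n_shared == 0L, 2, ifelse(n_shared == 1L, 2 / 3, 1 / 2))
}

criterion_c_factor <- function(nhp_among_trends) ifelse(nhp_among_trends, 1, 2)

#' Correction-factor assessment of a tentative wild card
#'
#' Evaluates the four enrichment criteria for one signal given the trend
#' context, and combines them multiplicatively.
#'
#' @param dscs Character vector of the signal's DSC strings.
#' @param signature The signal's classification signature (string or
#'   `nhp_signature`).
#' @param trend_dscs Character vector of trend (weak-signal) DSC strings.
#' @param trend_signatures Character vector of canonical signatures observed
#'   among trend signals.
#' @param nhp_predicate Predicate deciding whether the signal's NHP is
#'   "defined among the weak signals"; the default tests canonical-signature
#'   equality against `trend_signatures` and can be swapped for a looser
#'   reading.
#' @return A list of class `correction_assessment` with the four criterion
#'   inputs, the four factors and `combined_factor`.
#' @export
assess_correction <- function(dscs, signature, trend_dscs,
                              trend_signatures = character(),
                              nhp_predicate = NULL) {
  dscs <- vapply(dscs, function(d) format_dsc(as_dsc(d)), character(1),
                 USE.NAMES = FALSE)
  sig_canon <- format_signature(as_signature(signature))
  if (is.null(nhp_predicate))
    nhp_predicate <- function(sig, trend_sigs) sig %in% trend_sigs

  has_unspecific <- any(is_unspecific_dsc(dscs))
  n_dscs <- length(dscs)
  n_shared <- length(intersect(dscs, trend_dscs))
  among <- isTRUE(nhp_predicate(sig_canon, trend_signatures))

  fz <- criterion_z_factor(has_unspecific)
  fn <- criterion_n_factor(n_dscs)
  fs <- criterion_s_factor(n_shared)
  fc <- criterion_c_factor(among)
  structure(list(
    has_unspecific_dsc = has_unspecific,
    n_dscs = n_dscs,
    n_dscs_shared_with_trends = n_shared,
    nhp_among_weak_signals = among,
    factor_z = fz, factor_n = fn, factor_s = fs, factor_c = fc,
    combined_factor = fz * fn * fs * fc
  ), class = "correction_assessment")
}

#' Corrected novelty scores for tentative wild cards
#'
#' For every tentative wild-card signal: the raw score is the novelty of its
#' DSC *combination* (C = number of selected signals carrying exactly that
#' DSC set), the four correction criteria are assessed against the trend
#' context, and the corrected score is raw score times combined factor.
#' Signals with a zero factor (unspecific DSCs) are removed before ranking.
#'
#' @param db A `signal_db`.
#' @param selection A `quartile_selection` built from `db`'s spectrum.
#' @param nhp_predicate Passed to [assess_correction()].
#' @return A tibble of ranked wild-card results: `signal_id`, `dscs`,
#'   `signature`, `combo_count`, `raw_score`, criterion columns, the four
#'   factors, `combined_factor`, `corrected_score` and `rank`; sorted by
#'   corrected score descending, ties by `signal_id`.
#' @export
corrected_scores <- function(db, selection, nhp_predicate = NULL) {
  stopifnot(inherits(db, "signal_db"))
  long <- signal_dsc_long(db)
  total <- sum(db$signals$status == "selected")

  wc_ids <- selection$wildcard_signal_ids
  if (is.null(wc_ids)) wc_ids <- tentative_wildcard_signals(db, selection)
  if (!length(wc_ids)) {
    return(tibble::tibble(signal_id = character(), dscs = character(),
                          signature = character(), combo_count = integer(),
                          raw_score = numeric(), has_unspecific_dsc = logical(),
                          n_dscs = integer(), n_dscs_shared_with_trends = integer(),
                          nhp_among_weak_signals = logical(),
                          combined_factor = numeric(), corrected_score = numeric(),
                          rank = integer()))
  }

  sel <- db$signals[db$signals$status == "selected", ]
  dsc_lists <- strsplit(sel$dscs, ";", fixed = TRUE)
  combo_key <- vapply(dsc_lists, function(x) paste(sort(x), collapse = ";"),
                      character(1))
  combo_counts <- table(combo_key)

  trend_ids <- unique(long$signal_id[long$dsc %in% selection$trends])
  canon <- canonical_signatures(sel$signature)
  trend_signatures <- unique(canon[sel$signal_id %in% trend_ids])

  idx <- match(wc_ids, sel$signal_id)
  wc_lists <- dsc_lists[idx]
  n_dscs <- lengths(wc_lists)
  has_unspecific <- vapply(wc_lists, function(x) any(grepl("^[YZ]\\.", x)),
                           logical(1))
  n_shared <- vapply(wc_lists, function(x)
    length(intersect(x, selection$trends)), integer(1))
  if (is.null(nhp_predicate)) {
    among <- canon[idx] %in% trend_signatures
  } else {
    among <- vapply(canon[idx], function(s)
      isTRUE(nhp_predicate(s, trend_signatures)), logical(1))
  }
  combined <- criterion_z_factor(has_unspecific) * criterion_n_factor(n_dscs) *
    criterion_s_factor(n_shared) * criterion_c_factor(among)
  cc <- as.integer(combo_counts[combo_key[idx]])
  raw <- novelty_score(cc, total)
  out <- tibble::tibble(
    signal_id = sel$signal_id[idx],
    dscs = sel$dscs[idx],
    signature = sel$signature[idx],
    combo_count = cc,
    raw_score = raw,
    has_unspecific_dsc = has_unspecific,
    n_dscs = n_dscs,
    n_dscs_shared_with_trends = n_shared,
    nhp_among_weak_signals = among,
    combined_factor = combined,
    corrected_score = raw * combined
  )
  out <- out[out$combined_factor > 0, ]
  out <- out[order(-out$corrected_score, out$signal_id), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Final wild-card selection
#'
#' After correction the score distribution segregates; the default
#' `"max-cluster"` mode returns every signal attaining the maximal corrected
#' score (ties included, up to numerical noise), `"top-k"` the `k` best by
#' rank.
#'
#' @param results Ranked tibble from [corrected_scores()] (non-empty).
#' @param mode `"max-cluster"` or `"top-k"`.
#' @param k Number of results for `"top-k"`.
#' @param tol Absolute tolerance for score ties in `"max-cluster"`.
#' @return The selected rows of `results`.
#' @export
select_final_wildcards <- function(results, mode = c("max-cluster", "top-k"),
                                   k = 5, tol = 1e-9) {
  mode <- match.arg(mode)
  if (!nrow(results)) stop("no ranked wild-card results to select from",
                           call. = FALSE)
  if (mode == "max-cluster") {
    best <- max(results$corrected_score)
    results[results$corrected_score >= best - tol, ]
  } else {
    results[seq_len(min(k, nrow(results))), ]
  }
}
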