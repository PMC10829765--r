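# Data model and I/O for the detected-signal database.
#
# One row = one detected signal = one NHP. A multifunctional product is a
# single signal carrying several DSCs; it is never split into separate
# records. Discarded signals are retained for the scan tallies but do not
# feed the novelty pipeline.

signal_sources <- c("scopus", "epo", "clinicaltrials")
signal_statuses <- c("selected", "discarded")

signal_columns <- c("signal_id", "source", "scan_period", "status",
                    "discard_reason", "signature", "dscs", "source_ref")

#' Construct a signal database
#'
#' @param signals A data frame with columns `signal_id`, `source`,
#'   `scan_period`, `status`, `discard_reason`, `signature`, `dscs`
#'   (semicolon-joined DSC strings) and `source_ref`. Optional fields hold
#'   `""` when absent.
#' @param provenance Free-text metadata (scan strings, dates, generator
#'   settings).
#' @return An object of class `signal_db`.
#' @export
signal_db <- function(signals, provenance = character()) {
  signals <- tibble::as_tibble(signals)
  missing <- setdiff(signal_columns, names(signals))
  if (length(missing))
    stop("signal table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  signals <- signals[signal_columns]
  for (col in signal_columns) signals[[col]] <- as.character(signals[[col]])
  signals[is.na(signals)] <- ""
  validate_signals(signals)
  structure(list(signals = signals, provenance = as.character(provenance)),
            class = "signal_db")
}

#' @export
print.signal_db <- function(x, ...) {
  n_sel <- sum(x$signals$status == "selected")
  cat("<signal_db> ", nrow(x$signals), " signals (", n_sel, " selected, ",
      nrow(x$signals) - n_sel, " discarded)\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = "; "), "\n", sep = "")
  invisible(x)
}

# Row-level validation with row/field in every error message. Signatures and
# DSC strings are parsed once per distinct value, so large generated
# databases validate quickly.
validate_signals <- function(tbl) {
  fail <- function(row, field, msg)
    stop("signal table row ", row, ", field '", field, "': ", msg, call. = FALSE)

  if (anyDuplicated(tbl$signal_id)) {
    dup <- which(duplicated(tbl$signal_id))[1]
    fail(dup, "signal_id", paste0("duplicate id '", tbl$signal_id[dup], "'"))
  }
  bad <- which(!nzchar(tbl$signal_id))
  if (length(bad)) fail(bad[1], "signal_id", "empty id")
  bad <- which(!tbl$source %in% signal_sources)
  if (length(bad))
    fail(bad[1], "source", paste0("'", tbl$source[bad[1]], "' is not one of ",
                                  paste(signal_sources, collapse = ", ")))
  bad <- which(!nzchar(tbl$scan_period))
  if (length(bad)) fail(bad[1], "scan_period", "empty scan period")
  bad <- which(!tbl$status %in% signal_statuses)
  if (length(bad))
    fail(bad[1], "status", paste0("'", tbl$status[bad[1]], "' is not one of ",
                                  paste(signal_statuses, collapse = ", ")))
  discarded <- tbl$status == "discarded"
  bad <- which(discarded & !nzchar(tbl$discard_reason))
  if (length(bad)) fail(bad[1], "discard_reason",
                        "required for a discarded signal")

  sel <- which(!discarded)
  bad <- sel[!nzchar(tbl$signature[sel])]
  if (length(bad)) fail(bad[1], "signature", "required for a selected signal")
  bad <- sel[!nzchar(tbl$dscs[sel])]
  if (length(bad)) fail(bad[1], "dscs", "at least one DSC required for a selected signal")

  # parse each distinct signature / DSC once
  sigs <- unique(tbl$signature[sel])
  for (s in sigs) {
    ok <- tryCatch({ parse_signature(s); TRUE }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) fail(which(tbl$signature == s)[1], "signature", ok)
  }
  dsc_lists <- strsplit(tbl$dscs[sel], ";", fixed = TRUE)
  all_dscs <- unique(unlist(dsc_lists))
  # fast path: one regex covers the full DSC grammar; parse_dsc is only
  # invoked on failures, for its positional error message
  bad_dscs <- all_dscs[!grepl("^[A-Z]+\\.[A-Z]\\.[12]\\.[123]$", all_dscs)]
  for (d in bad_dscs) {
    ok <- tryCatch({ parse_dsc(d); TRUE }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) fail(sel[vapply(dsc_lists, function(x) d %in% x, logical(1))][1],
                          "dscs", ok)
  }
  dup <- vapply(dsc_lists, anyDuplicated, integer(1)) > 0L
  if (any(dup)) fail(sel[dup][1], "dscs", "duplicated DSC within one signal")
  invisible(tbl)
}

#' Read and write a signal database
#'
#' The CSV schema has the fixed header `signal_id, source, scan_period,
#' status, discard_reason, signature, dscs, source_ref`, with the `dscs`
#' column holding semicolon-joined DSC strings; JSON is an array of objects
#' with identical keys. Both are UTF-8 and round-trip losslessly; signatures
#' and DSCs are validated on read with the offending row and field named in
#' any error.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return `read_signals()` returns a `signal_db`; `write_signals()` returns
#'   `path` invisibly.
#' @export
read_signals <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    tbl <- readr::read_csv(path, na = character(),
                           col_types = readr::cols(.default = readr::col_character()))
    prov <- character()
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(obj)) {
      tbl <- obj
      prov <- character()
    } else {
      tbl <- obj$signals
      prov <- as.character(obj$provenance)
    }
    tbl[is.na(tbl)] <- ""
  }
  signal_db(tbl, provenance = prov)
}

#' @param db A `signal_db`.
#' @rdname read_signals
#' @export
write_signals <- function(db, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(db, "signal_db"))
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    readr::write_csv(db$signals, path, na = "")
  } else {
    jsonlite::write_json(list(provenance = db$provenance, signals = db$signals),
                         path, dataframe = "rows", auto_unbox = FALSE, pretty = FALSE)
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  stop("cannot infer format from extension '", ext, "'; pass format=", call. = FALSE)
}

#' Per-source, per-period scan tallies
#'
#' Summarizes the signal database the way a scan-results table reports it:
#' for each (source, scan period) stratum, the total results analysed
#' (`total_results`), the signals selected for the pipeline (`selected`) and
#' those discarded (`not_selected`), with `total_results = selected +
#' not_selected` by construction.
#'
#' @param db A `signal_db`.
#' @return A tibble with columns `source`, `scan_period`, `total_results`,
#'   `selected`, `not_selected`, ordered by source then period.
#' @seealso [selected_totals()]
#' @export
tally <- function(db) {
  stopifnot(inherits(db, "signal_db"))
  s <- db$signals
  out <- dplyr::summarise(
    dplyr::group_by(s, source = factor(source, levels = signal_sources),
                    scan_period = scan_period),
    selected = sum(status == "selected"),
    not_selected = sum(status == "discarded"),
    .groups = "drop")
  out$total_results <- out$selected + out$not_selected
  out$source <- as.character(out$source)
  dplyr::arrange(out[, c("source", "scan_period", "total_results",
                         "selected", "not_selected")],
                 match(source, signal_sources), scan_period)
}

#' Selected-signal totals per source
#'
#' @param db A `signal_db`.
#' @return Named integer vector of selected-signal counts, one per source.
#' @export
selected_totals <- function(db) {
  tl <- tally(db)
  agg <- dplyr::summarise(dplyr::group_by(tl, source), n = sum(selected),
                          .groups = "drop")
  out <- stats::setNames(integer(length(signal_sources)), signal_sources)
  out[agg$source] <- agg$n
  out
}

# Long view of the selected signals: one row per (signal, DSC).
signal_dsc_long <- function(db) {
  s <- db$signals[db$signals$status == "selected", ]
  lists <- strsplit(s$dscs, ";", fixed = TRUE)
  tibble::tibble(
    signal_id = rep(s$signal_id, lengths(lists)),
    source = rep(s$source, lengths(lists)),
    signature = rep(s$signature, lengths(lists)),
    dsc = unlist(lists)
  )
}

#' Per-source breakdown of a design solution
#'
#' Counts, for one DSC, how many selected signals carry it in each source
#' stratum. The counts sum to the DSC's frequency in the spectrum.
#'
#' @param db A `signal_db`.
#' @param dsc A DSC string (validated).
#' @return Named integer vector over the three sources.
#' @export
source_breakdown <- function(db, dsc) {
  stopifnot(inherits(db, "signal_db"))
  dsc <- format_dsc(as_dsc(dsc))
  long <- signal_dsc_long(db)
  hits <- long[long$dsc == dsc, ]
  out <- stats::setNames(integer(length(signal_sources)), signal_sources)
  if (nrow(hits)) {
    cnt <- table(hits$source)
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}
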