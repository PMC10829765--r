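# Regulatory-gap analysis: match prioritized NHP categories (trend DSCs and
# final wild cards) against a table of regulatory documents and flag
# insufficiently regulated categories.

regdb_sources <- c("ASTM", "ISO", "EMA", "FDA", "European Commission",
                   "OECD", "other")

#' Read a regulatory-document table
#'
#' CSV schema: `source`, `status`, `name`, `nhp_pattern`, where
#' `nhp_pattern` is a signature pattern possibly containing `"n"` wildcards
#' and `"0"` (undefined) codes. Every pattern is validated; an unparsable
#' pattern aborts with the offending row named. Document status (e.g.
#' "Under development") is carried through but never affects matching.
#'
#' @param path CSV path; defaults to the packaged nine-document fixture of
#'   galenic-NHP guidance.
#' @return A tibble of validated regulatory documents.
#' @export
read_regdb <- function(path = regdb_fixture_path()) {
  tbl <- readr::read_csv(path, na = character(),
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("source", "status", "name", "nhp_pattern")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("regulatory table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(tbl))) {
    ok <- tryCatch({ parse_signature(tbl$nhp_pattern[i], allow_wildcards = TRUE); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("regulatory table row ", i, " ('", tbl$name[i], "'): ", ok, call. = FALSE)
  }
  tibble::as_tibble(tbl[required])
}

#' @rdname read_regdb
#' @export
regdb_fixture_path <- function() {
  system.file("extdata", "regulatory_documents_galenic.csv",
              package = "nanoforesight", mustWork = TRUE)
}

#' Regulatory documents applicable to an NHP category
#'
#' Returns the documents whose `nhp_pattern` matches the query under
#' [matches_pattern()] semantics (position-wise set intersection, `"n"`
#' wildcard on either side). The query may itself be a pattern, e.g.
#' `"2.3.n.n"` for all galenic non-pharmacological NHPs.
#'
#' @param query A signature or pattern string (or parsed signature).
#' @param regdb Regulatory-document tibble from [read_regdb()] or
#'   [generate_regdb()].
#' @param lenient If `TRUE`, an undefined (`"0"`) position on either side
#'   also matches; strict matching treats `"0"` as a literal code.
#' @return The matching rows of `regdb`.
#' @examples
#' \donttest{
#' regdb <- read_regdb()
#' nrow(applicable_documents("2.3.n.n", regdb))  # 9
#' nrow(applicable_documents("2.3.3s.1", regdb)) # 6
#' }
#' @export
applicable_documents <- function(query, regdb, lenient = FALSE) {
  query <- as_signature(query, allow_wildcards = TRUE)
  pats <- lapply(regdb$nhp_pattern, parse_signature, allow_wildcards = TRUE)
  hit <- vapply(pats, function(p) pattern_pair_matches(query, p, lenient),
                logical(1))
  regdb[hit, ]
}

# Symmetric pattern-vs-pattern match: each position satisfied when either
# side is a wildcard or the code sets intersect.
pattern_pair_matches <- function(a, b, lenient = FALSE) {
  for (i in seq_len(4L)) {
    if ("n" %in% a[[i]] || "n" %in% b[[i]]) next
    if (lenient && (identical(a[[i]], "0") || identical(b[[i]], "0"))) next
    if (!length(intersect(a[[i]], b[[i]]))) return(FALSE)
  }
  TRUE
}

#' Regulatory gap report
#'
#' For each prioritized item — every trend DSC and every final wild card —
#' counts and lists the applicable regulatory documents, and flags the item
#' `insufficient` when no document addresses it. A trend DSC is queried
#' through the distinct signatures of the signals that carry it; its matched
#' set is the union over those signatures. For a multifunctional wild card
#' (any multivalued signature position), flagging additionally requires a
#' document to cover *all* codes of every multivalued position
#' (`coverage = "full"`, the default); intersection-level matches are still
#' reported in the counts. `coverage = "strict"` flags on the intersection
#' matches alone.
#'
#' @param db A `signal_db`.
#' @param selection A `quartile_selection` for `db`.
#' @param final_wildcards Result rows from [select_final_wildcards()].
#' @param regdb Regulatory-document tibble.
#' @param lenient Passed to the matching predicates.
#' @param coverage `"full"` or `"strict"` flagging rule for multifunctional
#'   items.
#' @return A tibble sorted by match count ascending: `item`, `kind`
#'   (`"trend"`/`"wildcard"`), `query`, `n_matched`, `matched`
#'   (semicolon-joined document names) and `insufficient`.
#' @export
gap_report <- function(db, selection, final_wildcards, regdb,
                       lenient = FALSE, coverage = c("full", "strict")) {
  coverage <- match.arg(coverage)
  long <- signal_dsc_long(db)

  # regdb patterns parsed once; same matching predicate as
  # applicable_documents()
  pats <- lapply(regdb$nhp_pattern, parse_signature, allow_wildcards = TRUE)
  matched_names <- function(query) {
    q <- as_signature(query, allow_wildcards = TRUE)
    regdb$name[vapply(pats, function(p) pattern_pair_matches(q, p, lenient),
                      logical(1))]
  }

  items <- list()
  for (d in selection$trends) {
    sigs <- unique(long$signature[long$dsc == d])
    docs <- unique(unlist(lapply(sigs, matched_names)))
    items[[length(items) + 1L]] <- tibble::tibble(
      item = d, kind = "trend", query = paste(sigs, collapse = " | "),
      n_matched = length(docs),
      matched = paste(docs, collapse = ";"),
      insufficient = length(docs) == 0L)
  }
  if (!is.null(final_wildcards) && nrow(final_wildcards)) {
    for (i in seq_len(nrow(final_wildcards))) {
      sig <- final_wildcards$signature[i]
      docs <- matched_names(sig)
      if (coverage == "full" && is_multivalued(sig)) {
        covered <- vapply(regdb$nhp_pattern, covers_signature, logical(1),
                          sig = sig, lenient = lenient)
        flag <- !any(covered)
      } else {
        flag <- length(docs) == 0L
      }
      items[[length(items) + 1L]] <- tibble::tibble(
        item = final_wildcards$signal_id[i], kind = "wildcard", query = sig,
        n_matched = length(docs),
        matched = paste(docs, collapse = ";"),
        insufficient = flag)
    }
  }
  out <- dplyr::bind_rows(items)
  out[order(out$n_matched, out$kind, out$item), ]
}
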