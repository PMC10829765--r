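# Grammar, validation and matching for NHP classification signatures and
# design-solution codes (DSCs).
#
# A classification signature is a four-position code
#   <mode of action>.<medical purpose>.<chemical composition>.<nanofabrication>
# e.g. "2.3.2.1". A position may hold several codes, rendered in parentheses
# ("2.(1.2.3).1.1" = a multifunctional product), and composition codes may
# carry an "s" suffix marking self-assembly in physiological medium ("3s").
# In pattern strings the literal "n" is a wildcard position; "0" (undefined)
# is an ordinary code, not a wildcard.

sig_position_names <- c("mode_of_action", "medical_purpose",
                        "chemical_composition", "nanofabrication")

sig_alphabets <- list(
  mode_of_action       = c("1", "2"),
  medical_purpose      = c("1", "2", "3"),
  chemical_composition = c("0", "1", "2", "3", "1s", "2s", "3s"),
  nanofabrication      = c("0", "1", "2")
)

# Canonical code order within a position: numeric part ascending, plain code
# before its self-assembling variant, wildcard "n" last.
sort_codes <- function(codes) {
  num <- suppressWarnings(as.integer(sub("s$", "", codes)))
  num[codes == "n"] <- 99L
  codes[order(num, grepl("s$", codes))]
}

# Split a signature string into top-level dot-separated tokens, respecting
# one level of parentheses. Errors on unbalanced parentheses.
split_positions <- function(raw, text = raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  depth <- 0L
  buf <- character()
  out <- list()
  for (ch in chars) {
    if (ch == "(") {
      depth <- depth + 1L
      if (depth > 1L) stop("nested parentheses in signature '", text, "'", call. = FALSE)
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses in signature '", text, "'", call. = FALSE)
    }
    if (ch == "." && depth == 0L) {
      out[[length(out) + 1L]] <- paste(buf, collapse = "")
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses in signature '", text, "'", call. = FALSE)
  out[[length(out) + 1L]] <- paste(buf, collapse = "")
  unlist(out)
}

#' Parse an NHP classification signature
#'
#' Parses the four-position classification signature used to index
#' nanotechnology-enabled health products: mode of action, medical purpose,
#' chemical composition and nanofabrication approach, e.g. `"2.3.2.1"`.
#' Multivalued positions are parenthesized (`"2.(1.2.3).1.1"`) and
#' composition codes may carry a self-assembly flag (`"2.3.3s.1"`).
#' Whitespace inside the string is ignored, so `"2.3.3 s.1"` parses the same
#' as `"2.3.3s.1"`.
#'
#' @param text A single signature string.
#' @param allow_wildcards If `TRUE`, the literal `"n"` is accepted in any
#'   position as a wildcard; used for matching patterns such as `"2.3.n.n"`.
#' @return An object of class `nhp_signature`: a named list of four character
#'   vectors of codes, one per position, each sorted canonically.
#' @examples
#' parse_signature("2.3.2.1")
#' parse_signature("2.(1.2.3).1.1")$medical_purpose
#' @seealso [format_signature()], [matches_pattern()]
#' @export
parse_signature <- function(text, allow_wildcards = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("signature must be a single character string", call. = FALSE)
  raw <- gsub("[[:space:]]+", "", text)
  if (!nzchar(raw)) stop("empty signature string", call. = FALSE)
  if (grepl("(", raw, fixed = TRUE) || grepl(")", raw, fixed = TRUE)) {
    toks <- split_positions(raw, text)
  } else {
    toks <- strsplit(raw, ".", fixed = TRUE)[[1]]
  }
  if (length(toks) != 4L)
    stop("signature '", text, "' has ", length(toks),
         " positions; expected 4", call. = FALSE)
  pos <- vector("list", 4L)
  names(pos) <- sig_position_names
  for (i in seq_len(4L)) {
    tok <- toks[i]
    if (grepl("^\\(.*\\)$", tok)) {
      codes <- strsplit(substr(tok, 2L, nchar(tok) - 1L), ".", fixed = TRUE)[[1]]
    } else {
      codes <- tok
    }
    if (length(codes) == 0L || any(!nzchar(codes)))
      stop("empty code in position ", sig_position_names[i],
           " of signature '", text, "'", call. = FALSE)
    legal <- sig_alphabets[[i]]
    if (allow_wildcards) legal <- c(legal, "n")
    bad <- setdiff(codes, legal)
    if (length(bad))
      stop("illegal code '", bad[1], "' in position ", sig_position_names[i],
           " of signature '", text, "'", call. = FALSE)
    if (anyDuplicated(codes))
      stop("duplicated code in position ", sig_position_names[i],
           " of signature '", text, "'", call. = FALSE)
    pos[[i]] <- sort_codes(codes)
  }
  structure(pos, class = "nhp_signature")
}

#' Format a classification signature canonically
#'
#' Inverse of [parse_signature()]: renders dot-separated positions,
#' parenthesizing multivalued positions with codes in ascending order and
#' appending the self-assembly flag without a space. Parsing a canonical
#' string and formatting it back is the identity.
#'
#' @param sig An `nhp_signature`, or a signature string (normalized by a
#'   parse/format round trip).
#' @return A single canonical signature string.
#' @examples
#' format_signature(parse_signature("2.3.3 s.1")) # "2.3.3s.1"
#' @export
format_signature <- function(sig) {
  sig <- as_signature(sig)
  toks <- vapply(sig, function(codes) {
    if (length(codes) > 1L) paste0("(", paste(codes, collapse = "."), ")")
    else codes
  }, character(1))
  paste(toks, collapse = ".")
}

#' @export
print.nhp_signature <- function(x, ...) {
  cat("<nhp_signature> ", format_signature(x), "\n", sep = "")
  invisible(x)
}

# Vectorized canonicalization of signature strings; each distinct value is
# parsed once.
canonical_signatures <- function(x) {
  u <- unique(x)
  canon <- vapply(u, function(s) format_signature(parse_signature(s)),
                  character(1))
  unname(canon[match(x, u)])
}

# Coerce a string or nhp_signature, optionally allowing "n" wildcards.
as_signature <- function(x, allow_wildcards = FALSE) {
  if (inherits(x, "nhp_signature")) return(x)
  parse_signature(x, allow_wildcards = allow_wildcards)
}

# TRUE iff any position holds more than one code (multifunctional /
# multicomposite product).
is_multivalued <- function(sig) {
  sig <- as_signature(sig)
  any(lengths(sig) > 1L)
}

#' Match a signature against a wildcard pattern
#'
#' A pattern is a signature string in which any position may be the literal
#' `"n"`, matching anything (e.g. `"2.3.n.n"` selects galenic products with a
#' non-pharmacological action). A non-wildcard pattern position matches when
#' its code set intersects the signature's code set, so the multifunctional
#' signature `"2.(1.2.3).1.1"` matches `"n.2.n.n"`. The code `"0"`
#' (undefined) is an ordinary literal; with `lenient = TRUE` a position in
#' which either side is exactly `"0"` is treated as satisfied.
#'
#' @param sig An `nhp_signature` or signature string.
#' @param pattern A pattern string (or parsed pattern) possibly containing
#'   `"n"` wildcards.
#' @param lenient If `TRUE`, an undefined (`"0"`) position on either side
#'   also matches.
#' @return `TRUE` or `FALSE`.
#' @examples
#' matches_pattern("2.3.2.1", "2.3.n.n")      # TRUE
#' matches_pattern("2.3.1.0", "2.3.3s.n")     # FALSE
#' @export
matches_pattern <- function(sig, pattern, lenient = FALSE) {
  sig <- as_signature(sig)
  pattern <- as_signature(pattern, allow_wildcards = TRUE)
  for (i in seq_len(4L)) {
    p <- pattern[[i]]
    s <- sig[[i]]
    if ("n" %in% p) next
    if (lenient && (identical(p, "0") || identical(s, "0"))) next
    if (!length(intersect(p, s))) return(FALSE)
  }
  TRUE
}

# Coverage predicate used when flagging regulatory gaps for multifunctional
# products: the document pattern must cover ALL codes of every signature
# position (wildcard positions cover everything).
covers_signature <- function(pattern, sig, lenient = FALSE) {
  sig <- as_signature(sig)
  pattern <- as_signature(pattern, allow_wildcards = TRUE)
  for (i in seq_len(4L)) {
    p <- pattern[[i]]
    s <- sig[[i]]
    if ("n" %in% p) next
    if (lenient && (identical(p, "0") || identical(s, "0"))) next
    if (!all(s %in% p)) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Design-solution codes

#' Parse a design-solution code (DSC)
#'
#' A DSC encodes the attribute by which an NHP addresses one of six design
#' problems, as `<solution id>.<effect qualifier>.<mode>.<purpose>`, e.g.
#' `"B.T.2.3"` (molecular building block nanocarrier: non-pharmacological
#' mode, galenic purpose). The solution id is one or more letters; `"Y"` and
#' `"Z"` are reserved for unspecific solutions from which no conclusion can
#' be drawn.
#'
#' @param text A single DSC string.
#' @param descriptor Optional free-text descriptor attached to the parsed
#'   code.
#' @return An object of class `dsc` with fields `solution_id`,
#'   `effect_qualifier`, `mode_of_action`, `medical_purpose`, `descriptor`
#'   and `unspecific`.
#' @examples
#' parse_dsc("B.T.2.3")
#' parse_dsc("Z.T.2.1")$unspecific
#' @export
parse_dsc <- function(text, descriptor = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("DSC must be a single character string", call. = FALSE)
  raw <- gsub("[[:space:]]+", "", text)
  toks <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (length(toks) != 4L)
    stop("DSC '", text, "' has ", length(toks), " tokens; expected 4", call. = FALSE)
  if (!grepl("^[A-Z]+$", toks[1]))
    stop("DSC '", text, "': solution id must be one or more capital letters", call. = FALSE)
  if (!grepl("^[A-Z]$", toks[2]))
    stop("DSC '", text, "': effect qualifier must be a single capital letter", call. = FALSE)
  if (!toks[3] %in% c("1", "2"))
    stop("DSC '", text, "': mode of action must be 1 or 2", call. = FALSE)
  if (!toks[4] %in% c("1", "2", "3"))
    stop("DSC '", text, "': medical purpose must be 1, 2 or 3", call. = FALSE)
  structure(list(
    solution_id = toks[1],
    effect_qualifier = toks[2],
    mode_of_action = toks[3],
    medical_purpose = toks[4],
    descriptor = descriptor,
    unspecific = toks[1] %in% c("Y", "Z")
  ), class = "dsc")
}

#' Format a design-solution code canonically
#'
#' @param dsc A `dsc` object or DSC string.
#' @return The canonical `"<id>.<qualifier>.<mode>.<purpose>"` string.
#' @export
format_dsc <- function(dsc) {
  dsc <- as_dsc(dsc)
  paste(dsc$solution_id, dsc$effect_qualifier,
        dsc$mode_of_action, dsc$medical_purpose, sep = ".")
}

#' @export
print.dsc <- function(x, ...) {
  cat("<dsc> ", format_dsc(x),
      if (x$unspecific) " (unspecific)" else "",
      if (!is.null(x$descriptor)) paste0(" - ", x$descriptor) else "",
      "\n", sep = "")
  invisible(x)
}

as_dsc <- function(x) {
  if (inherits(x, "dsc")) return(x)
  parse_dsc(x)
}

# TRUE for reserved Y/Z solution ids (vectorized over DSC strings).
is_unspecific_dsc <- function(dsc) {
  if (inherits(dsc, "dsc")) return(dsc$unspecific)
  vapply(dsc, function(d) as_dsc(d)$unspecific, logical(1), USE.NAMES = FALSE)
}

#' The six NHP design-problem categories
#'
#' @return Character vector of the six category labels: the mode-of-action by
#'   medical-purpose combinations under which design solutions compete.
#' @export
design_problem_categories <- function() {
  c("pharmacological action, therapeutic (treating) effect",
    "pharmacological action, therapeutic (prophylactic) effect",
    "non-pharmacological action, therapeutic effect",
    "diagnostic effect (not in vitro)",
    "diagnostic effect (in vitro)",
    "galenic effect")
}

#' Map a DSC to its design-problem category
#'
#' Design problems are the arenas within which design solutions compete for
#' novelty: combinations of primary mode of action (pharmacological /
#' immunological / metabolic vs. not) and medical purpose (therapeutic,
#' diagnostic, galenic). Two splits are not carried by the purpose digit and
#' are therefore data-driven: the treating/prophylactic split for
#' pharmacological therapeutics is carried by the DSC effect qualifier
#' (`prophylactic_qualifier`, default `"P"`; every observed code uses `"T"`),
#' and the in vitro diagnostic split by an explicit DSC list (`ivd_dscs`).
#'
#' @param dsc A `dsc` object or DSC string.
#' @param prophylactic_qualifier Effect-qualifier letter marking a
#'   prophylactic solution.
#' @param ivd_dscs Character vector of DSC strings to classify as in vitro
#'   diagnostic.
#' @return One of the six labels of [design_problem_categories()].
#' @examples
#' design_problem("B.T.2.3") # galenic effect
#' @export
design_problem <- function(dsc, prophylactic_qualifier = "P",
                           ivd_dscs = character()) {
  dsc <- as_dsc(dsc)
  cats <- design_problem_categories()
  p <- dsc$medical_purpose
  if (p == "3") return(cats[6])
  if (p == "2") {
    if (format_dsc(dsc) %in% ivd_dscs) return(cats[5])
    return(cats[4])
  }
  # purpose 1: therapeutic
  if (dsc$mode_of_action == "2") return(cats[3])
  if (identical(dsc$effect_qualifier, prophylactic_qualifier)) return(cats[2])
  cats[1]
}

#' Read a DSC dictionary
#'
#' Reads a CSV with columns `dsc_code`, `descriptor`, `definition` mapping
#' design-solution codes to their human-readable meaning. The packaged
#' dictionary (`dsc_dictionary_path()`) contains every DSC printed in the
#' study's trend and wild-card tables.
#'
#' @param path Path to the dictionary CSV; defaults to the packaged fixture.
#' @return A tibble with one validated row per DSC.
#' @export
read_dsc_dictionary <- function(path = dsc_dictionary_path()) {
  dict <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("dsc_code", "descriptor", "definition")
  missing <- setdiff(required, names(dict))
  if (length(missing))
    stop("DSC dictionary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(dict))) parse_dsc(dict$dsc_code[i])
  tibble::as_tibble(dict[required])
}

#' @rdname read_dsc_dictionary
#' @export
dsc_dictionary_path <- function() {
  system.file("extdata", "dsc_dictionary.csv", package = "nanoforesight",
              mustWork = TRUE)
}
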