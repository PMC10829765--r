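# Shared helpers: tiny in-code signal databases and independent oracles.

sig_row <- function(id, dscs, signature = "2.3.2.1", source = "scopus",
                    period = "1", status = "selected", reason = "",
                    ref = "") {
  tibble::tibble(signal_id = id, source = source, scan_period = period,
                 status = status, discard_reason = reason,
                 signature = signature, dscs = dscs, source_ref = ref)
}

make_db <- function(...) signal_db(dplyr::bind_rows(...))

# Independent oracle for quartile selection: expand the descending-frequency
# spectrum into unit signals with positions 1..M and classify each DSC by
# the positions its units occupy, instead of cumulative sums.
oracle_selection <- function(dscs, counts, total, q1 = 0.25, q3 = 0.75) {
  ord <- order(-counts, dscs)
  dscs <- dscs[ord]
  counts <- counts[ord]
  owner <- rep(seq_along(dscs), counts)
  pos <- seq_along(owner)
  first <- tapply(pos, owner, min)
  last <- tapply(pos, owner, max)
  list(trends = dscs[first < q1 * total + 1],
       wildcards = dscs[last > q3 * total])
}

# A random valid classification signature (possibly multivalued).
random_signature <- function() {
  pick <- function(alphabet) {
    k <- sample(seq_along(alphabet), 1, prob = c(0.8, rep(0.2 / (length(alphabet) - 1), length(alphabet) - 1)))
    sample(alphabet, k)
  }
  alph <- list(c("1", "2"), c("1", "2", "3"),
               c("0", "1", "2", "3", "1s", "2s", "3s"), c("0", "1", "2"))
  toks <- vapply(alph, function(a) {
    codes <- pick(a)
    if (length(codes) > 1) paste0("(", paste(codes, collapse = "."), ")")
    else codes
  }, character(1))
  paste(toks, collapse = ".")
}

# A random valid DSC string.
random_dsc <- function() {
  id <- paste(sample(LETTERS, sample(1:2, 1), replace = TRUE), collapse = "")
  paste(id, sample(LETTERS, 1), sample(1:2, 1), sample(1:3, 1), sep = ".")
}
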