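test_that("the nonzero correction-factor grid matches hand-computed products", {
  n_factor <- c("1" = 1, "2" = 3 / 2, "3" = 2)        # 1, 2, >2 DSCs
  s_factor <- c("0" = 2, "1" = 2 / 3, "2" = 1 / 2)    # 0, 1, >1 shared
  c_factor <- c(yes = 1, no = 2)
  grid <- expand.grid(n = 1:3, s = 0:2, among = c(TRUE, FALSE))
  expect_identical(nrow(grid), 18L)
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; s <- grid$s[i]; among <- grid$among[i]
    expected <- n_factor[[as.character(n)]] * s_factor[[as.character(s)]] *
      c_factor[[if (among) "yes" else "no"]]
    got <- nanoforesight:::criterion_z_factor(FALSE) *
      nanoforesight:::criterion_n_factor(n) *
      nanoforesight:::criterion_s_factor(s) *
      nanoforesight:::criterion_c_factor(among)
    expect_equal(got, expected)
    # feasible combinations are reproduced through a full assessment
    if (s <= n) {
      dscs <- sprintf("Q%s.T.1.1", LETTERS[seq_len(n)])
      a <- assess_correction(dscs, "1.1.1.1",
                             c(dscs[seq_len(s)], "TR.T.1.1"),
                             trend_signatures = if (among) "1.1.1.1" else "2.2.2.2")
      expect_equal(a$combined_factor, expected)
      expect_false(a$has_unspecific_dsc)
    }
  }
  # combined factor range over the whole grid
  nonzero <- as.vector(outer(n_factor, s_factor) %o% c_factor)
  expect_true(all(nonzero >= 1 / 3 & nonzero <= 8))
})

test_that("assessment examples multiply out as printed", {
  # 3 DSCs, nothing shared, NHP not among trends, no Y/Z -> 1*2*2*2 = 8
  a <- assess_correction(c("F.T.2.1", "A.T.2.2", "P.T.2.3"), "2.(1.2.3).1.1",
                         c("B.T.2.3", "E.T.2.1", "C.T.2.3"),
                         trend_signatures = c("2.3.2.1", "2.1.1.0"))
  expect_equal(a$combined_factor, 8)

  # an unspecific DSC annihilates the factor
  z <- assess_correction(c("A.T.2.2", "Z.T.2.1"), "2.2.1.1", "B.T.2.3")
  expect_true(z$has_unspecific_dsc)
  expect_equal(z$combined_factor, 0)

  # 1 DSC shared with a trend, signature among trend NHPs -> 1*1*(2/3)*1
  b <- assess_correction("B.T.2.3", "2.3.2.1", c("B.T.2.3", "E.T.2.1"),
                         trend_signatures = "2.3.2.1")
  expect_equal(b$combined_factor, 2 / 3)

  # the trend-NHP predicate is pluggable
  never <- assess_correction("B.T.2.3", "2.3.2.1", "B.T.2.3",
                             trend_signatures = "2.3.2.1",
                             nhp_predicate = function(sig, trends) FALSE)
  expect_equal(never$factor_c, 2)
})

test_that("corrected_score is monotone in the criteria", {
  raw <- novelty_score(1, 50)
  base <- function(n, s, among) {
    dscs <- sprintf("Q%s.T.1.1", LETTERS[seq_len(n)])
    assess_correction(dscs, "1.1.1.1",
                      c(dscs[seq_len(s)], "TR.T.1.1"),
                      trend_signatures = if (among) "1.1.1.1" else "2.2.2.2"
    )$combined_factor * raw
  }
  # more DSCs never decreases the corrected score
  expect_true(base(1, 0, FALSE) <= base(2, 0, FALSE))
  expect_true(base(2, 0, FALSE) <= base(3, 0, FALSE))
  # more shared DSCs never increases it
  expect_true(base(3, 0, FALSE) >= base(3, 1, FALSE))
  expect_true(base(3, 1, FALSE) >= base(3, 2, FALSE))
  # sharing the trend NHP halves it
  expect_equal(base(3, 0, TRUE) * 2, base(3, 0, FALSE))
})

# A 24-signal database with one dominant trend DSC and an assorted tail:
# Q1 = 6 selects only A.T.1.1 (count 8); Q3 = 18 leaves the singleton tail.
enrichment_db <- function() {
  rows <- list()
  for (i in 1:8) rows[[length(rows) + 1]] <-
    sig_row(sprintf("t%02d", i), "A.T.1.1", signature = "1.1.1.1")
  for (i in 1:6) rows[[length(rows) + 1]] <-
    sig_row(sprintf("m%02d", i), "M.T.1.1", signature = "1.1.2.1")
  for (i in 1:4) rows[[length(rows) + 1]] <-
    sig_row(sprintf("n%02d", i), "N.T.2.1", signature = "2.1.2.1")
  rows[[length(rows) + 1]] <- sig_row("w1", "QA.T.2.1;QB.T.2.2;QC.T.2.3",
                                      signature = "2.(1.2.3).1.1")
  rows[[length(rows) + 1]] <- sig_row("w2", "QD.T.2.1;QE.T.2.2",
                                      signature = "2.(1.2).1.1")
  rows[[length(rows) + 1]] <- sig_row("w3", "A.T.1.1;QF.T.2.2",
                                      signature = "1.(1.2).1.1")
  rows[[length(rows) + 1]] <- sig_row("w4", "QG.T.1.1", signature = "1.1.1.1")
  rows[[length(rows) + 1]] <- sig_row("w5", "QH.T.1.1;Z.T.1.1",
                                      signature = "1.1.3.1")
  rows[[length(rows) + 1]] <- sig_row("w6", "QI.T.1.1", signature = "1.1.3s.1")
  make_db(dplyr::bind_rows(rows))
}

test_that("corrected_scores ranks tentative wild cards and drops zero factors", {
  db <- enrichment_db()
  spec <- build_spectrum(db)
  sel <- quartile_selection(spec, db)
  expect_identical(sel$trends, "A.T.1.1")

  res <- corrected_scores(db, sel)
  # w3 carries the trend DSC so is not a tentative wild card; w5 carries Z
  # and is removed after assessment
  expect_false("w3" %in% res$signal_id)
  expect_false("w5" %in% res$signal_id)
  expect_true(all(res$combined_factor > 0))
  expect_identical(res$rank, seq_len(nrow(res)))
  expect_true(all(diff(res$corrected_score) <= 0))
  expect_equal(res$corrected_score, res$raw_score * res$combined_factor)

  # each row agrees with a fresh scalar assessment (dual route)
  long <- nanoforesight:::signal_dsc_long(db)
  trend_ids <- unique(long$signal_id[long$dsc %in% sel$trends])
  trend_sigs <- unique(long$signature[match(trend_ids, long$signal_id)])
  for (i in seq_len(nrow(res))) {
    a <- assess_correction(strsplit(res$dscs[i], ";")[[1]], res$signature[i],
                           sel$trends, trend_sigs)
    expect_equal(res$combined_factor[i], a$combined_factor)
  }

  # the triple-DSC, nothing-shared, new-NHP signal wins
  expect_identical(res$signal_id[1], "w1")
  expect_equal(res$combined_factor[1], 8)
  # w4 shares the trend NHP signature 1.1.1.1 -> factor_c = 1
  expect_equal(res$combined_factor[res$signal_id == "w4"], 1 * 1 * 2 * 1)
})

test_that("the raw score is the novelty of the exact DSC combination", {
  db <- make_db(
    sig_row("x1", "QA.T.1.1;QB.T.1.1", signature = "1.1.1.1"),
    sig_row("x2", "QB.T.1.1;QA.T.1.1", signature = "1.1.2.1"),
    sig_row("x3", "QA.T.1.1", signature = "1.1.1.1"),
    sig_row("t1", "TR.T.1.1", signature = "2.1.1.1"),
    sig_row("t2", "TR.T.1.1", signature = "2.1.1.1")
  )
  sel <- list(trends = "TR.T.1.1", wildcard_dscs = c("QA.T.1.1", "QB.T.1.1"),
              wildcard_signal_ids = NULL)
  res <- corrected_scores(db, sel)
  # x1 and x2 share the same combination regardless of DSC order: C = 2
  expect_equal(res$combo_count[res$signal_id %in% c("x1", "x2")], c(2L, 2L))
  expect_equal(res$combo_count[res$signal_id == "x3"], 1L)
  expect_equal(res$raw_score[res$signal_id == "x3"], novelty_score(1, 5))
})

test_that("final wild cards come from the maximal corrected-score cluster", {
  res <- tibble::tibble(
    signal_id = sprintf("s%d", 1:6),
    corrected_score = c(79.9, 79.9, 79.9, 39.9, 20, 10),
    rank = 1:6)
  top <- select_final_wildcards(res)
  expect_identical(top$signal_id, c("s1", "s2", "s3"))

  all_tied <- tibble::tibble(signal_id = c("a", "b"),
                             corrected_score = c(5, 5), rank = 1:2)
  expect_identical(nrow(select_final_wildcards(all_tied)), 2L)

  expect_identical(select_final_wildcards(res, mode = "top-k", k = 1)$signal_id, "s1")
  expect_error(select_final_wildcards(res[0, ]), "no ranked")
})

test_that("end-to-end enrichment on the default synthetic database", {
  db <- generate_signals(generator_config(seed = 99))
  sel <- quartile_selection(build_spectrum(db), db)
  res <- corrected_scores(db, sel)
  fin <- select_final_wildcards(res)
  expect_identical(nrow(fin), 5L)
  expect_true(all(fin$n_dscs == 3))
  expect_true(all(fin$combined_factor == 8))
  expect_true(all(round_half_up(fin$raw_score, 2) == 9.99))
  expect_true(all(fin$combo_count == 1))
})
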