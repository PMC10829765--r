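test_that("build_spectrum counts every DSC of every selected signal once", {
  db <- make_db(
    sig_row("a", "A.T.1.1;B.T.2.3", signature = "1.1.1.1"),
    sig_row("b", "A.T.1.1", signature = "1.1.1.1"),
    sig_row("c", "", signature = "", status = "discarded", reason = "noise")
  )
  spec <- build_spectrum(db)
  expect_identical(attr(spec, "total"), 2L)
  expect_identical(spec$count[spec$dsc == "A.T.1.1"], 2L)
  expect_identical(spec$count[spec$dsc == "B.T.2.3"], 1L)

  one <- build_spectrum(make_db(sig_row("a", "A.T.1.1", signature = "1.1.1.1")))
  expect_identical(nrow(one), 1L)
  expect_identical(attr(one, "total"), 1L)
})

test_that("novelty_score matches the closed form and its printed values", {
  expect_equal(round_half_up(novelty_score(95, 836), 2), 8.86)
  expect_equal(round_half_up(novelty_score(61, 836), 2), 9.27)
  expect_equal(round_half_up(novelty_score(1, 836), 2), 9.99)
  expect_equal(novelty_score(10, 10), 0)
  expect_error(novelty_score(5, 4), "1 <= C <= T")
  expect_error(novelty_score(1, 0), "positive")

  # strictly decreasing in C, bounded by 10(T-1)/T
  for (T_total in c(7, 50, 836)) {
    s <- novelty_score(seq_len(T_total), T_total)
    expect_true(all(diff(s) < 0))
    expect_true(all(s >= 0 & s <= 10 * (T_total - 1) / T_total))
  }
})

test_that("rounding of display scores is half-up", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(9.985, 2), 9.99)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("cumulative table accumulates in descending-frequency order", {
  spec <- new_spectrum(c(a = 95, b = 61, c = 61, d = 45), total = 836)
  ct <- cumulative_table(spec)
  expect_identical(ct$cum_count[1:3], c(95L, 156L, 217L))
  expect_true(all(diff(ct$cum_percent) >= 0))
  expect_equal(ct$cum_percent[nrow(ct)], 100)

  single <- cumulative_table(new_spectrum(c(a = 7)))
  expect_identical(nrow(single), 1L)
  expect_equal(single$cum_percent, 100)

  uni <- cumulative_table(new_spectrum(c(a = 5, b = 5, c = 5, d = 5)))
  expect_equal(uni$cum_percent, c(25, 50, 75, 100))
})

test_that("Q1 rule includes the crossing DSC and reports represented signals", {
  # head 95/61/61 over a tail of counts <= 45 summing to T = 836
  counts <- c(95, 61, 61, rep(45, 3), rep(20, 10), rep(2, 100), rep(1, 84))
  spec <- new_spectrum(stats::setNames(counts, sprintf("D%03d.T.1.1", seq_along(counts))))
  expect_identical(attr(spec, "total"), 836L)
  ws <- select_weak_signals(spec, 0.25)
  expect_length(ws$dscs, 3)
  expect_identical(ws$signal_count, 217L)

  # single-DSC spectrum: the lone DSC is the trend
  expect_identical(select_weak_signals(new_spectrum(c(a = 100)))$dscs, "a")

  # uniform singleton spectrum: exactly the first DSC in tie-broken order
  uni <- new_spectrum(c(b = 1, d = 1, a = 1, c = 1))
  expect_identical(select_weak_signals(uni)$dscs, "a")
})

test_that("Q3 rule selects the tail and flags degenerate overlap", {
  counts <- c(10, rep(1, 10))
  spec <- new_spectrum(stats::setNames(counts, sprintf("D%02d", seq_along(counts))))
  wc <- select_tentative_wildcards(spec)
  # Q3 = 15: the singleton tail past it is selected
  expect_true(all(spec$count[spec$dsc %in% wc$dscs] == 1))
  expect_false(wc$degenerate)
  oracle <- oracle_selection(spec$dsc, spec$count, attr(spec, "total"))
  expect_setequal(wc$dscs, oracle$wildcards)

  # a single-entry spectrum is degenerate: no wild card distinct from the trend
  expect_warning(deg <- select_tentative_wildcards(new_spectrum(c(a = 100))),
                 "degenerate")
  expect_length(deg$dscs, 0)
  expect_true(deg$degenerate)
})

test_that("quartile selection equals the unit-expansion oracle on small spectra", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    counts <- sample(1:8, n, replace = TRUE)
    while (sum(counts) > 50) counts <- counts[-1]
    if (!length(counts)) next
    dscs <- sprintf("S%02d", sample(99, length(counts)))
    spec <- new_spectrum(stats::setNames(counts, dscs))
    total <- attr(spec, "total")
    q1 <- sample(c(0.2, 0.25, 0.3), 1)
    q3 <- sample(c(0.7, 0.75, 0.8), 1)
    oracle <- oracle_selection(dscs, counts, total, q1, q3)
    ws <- select_weak_signals(spec, q1)
    expect_setequal(ws$dscs, oracle$trends)
    wc <- suppressWarnings(select_tentative_wildcards(spec, q3, q1))
    expect_setequal(wc$dscs, setdiff(oracle$wildcards, oracle$trends))
  }
})

test_that("trend and wild-card sets never overlap on non-degenerate spectra", {
  set.seed(5)
  for (i in 1:50) {
    counts <- sample(1:10, sample(4:12, 1), replace = TRUE)
    spec <- new_spectrum(stats::setNames(counts, sprintf("S%02d", seq_along(counts))))
    sel <- suppressWarnings(quartile_selection(spec))
    expect_length(intersect(sel$trends, sel$wildcard_dscs), 0)
  }
})

test_that("planted trends are recovered from synthetic databases", {
  for (s in 1:15) {
    db <- generate_signals(generator_config(seed = s))
    sel <- quartile_selection(build_spectrum(db))
    expect_setequal(sel$trends, c("B.T.2.3", "E.T.2.1", "C.T.2.3"))
    expect_identical(sel$trend_signal_count, 217L)
  }
})

test_that("tentative wild-card signals carry a tail DSC and no trend DSC", {
  db <- generate_signals(generator_config(seed = 2))
  spec <- build_spectrum(db)
  sel <- quartile_selection(spec, db)
  long <- nanoforesight:::signal_dsc_long(db)
  for (id in sel$wildcard_signal_ids) {
    dscs <- long$dsc[long$signal_id == id]
    expect_true(any(dscs %in% sel$wildcard_dscs))
    expect_false(any(dscs %in% sel$trends))
  }
})
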