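win <- process_window() # HPC default, 100-225 C

test_that("assessment applies the window and threshold rules", {
  # strong negative enthalpy in window: promising
  a <- assess_coformer("diacid_like", -3.0, 130, "solid", win)
  expect_identical(a$promise_class, "promising")
  expect_true(a$in_window)
  # positive enthalpy in window: unfavorable, like the negative control
  b <- assess_coformer("ornithine_like", 0.4, 140, "solid", win)
  expect_identical(b$promise_class, "unfavorable")
  # between threshold and zero: possible
  expect_identical(
    assess_coformer("weak", -1.2, 150, "solid", win)$promise_class,
    "possible")
  # window bounds are closed
  expect_true(assess_coformer("edge_lo", -3, 100, "solid", win)$in_window)
  expect_true(assess_coformer("edge_hi", -3, 225, "solid", win)$in_window)
  expect_identical(
    assess_coformer("edge_thr", -2, 150, "solid", win)$promise_class,
    "promising")
  # exclusions: liquid/waxy or melting outside the window
  expect_identical(
    assess_coformer("oil", -4, NA, "liquid", win)$promise_class,
    "excluded_low_tm")
  expect_identical(
    assess_coformer("wax", -4, NA, "waxy", win)$promise_class,
    "excluded_low_tm")
  expect_identical(
    assess_coformer("low", -4, 60, "solid", win)$promise_class,
    "excluded_low_tm")
  expect_identical(
    assess_coformer("high", -4, 280, "decomposes", win)$promise_class,
    "excluded_high_tm")
  # a candidate with neither melting point nor liquid/waxy flag is an error
  expect_error(assess_coformer("mystery", -1, NA, "solid", win), "neither")
  expect_error(assess_coformer("nohex", NA, 150, "solid", win), "h_ex")
})

test_that("classification is total and monotone in h_ex and Tm", {
  set.seed(23)
  classes <- c("promising", "possible", "unfavorable",
               "excluded_low_tm", "excluded_high_tm")
  for (i in 1:50) {
    hx <- stats::runif(1, -6, 3)
    tm <- stats::runif(1, 30, 330)
    a <- assess_coformer("x", hx, tm, "solid", win)
    expect_true(a$promise_class %in% classes)
    # more negative h_ex never worsens the class
    better <- assess_coformer("x", hx - 1, tm, "solid", win)
    rank_of <- function(cl) match(cl, c("promising", "possible",
                                        "unfavorable", "excluded_low_tm",
                                        "excluded_high_tm"))
    if (!grepl("^excluded", a$promise_class)) {
      expect_lte(rank_of(better$promise_class), rank_of(a$promise_class))
    }
    # moving Tm into the window never causes exclusion
    inside <- assess_coformer("x", hx, 150, "solid", win)
    expect_false(grepl("^excluded", inside$promise_class))
  }
})

test_that("ranking sorts by enthalpy with melting-point then name tiebreaks", {
  mk <- function(name, hx, tm) assess_coformer(name, hx, tm, "solid", win)
  ass <- rank_candidates(list(mk("a", -3.1, 180), mk("b", -2.5, 140),
                              mk("c", 0.4, 150)))
  expect_identical(ass$name[1:3], c("a", "b", "c"))
  expect_identical(ass$rank[1:3], 1:3)
  # equal enthalpy: lower melting point first
  tie <- rank_candidates(list(mk("hot", -2, 170), mk("cold", -2, 130)))
  expect_identical(tie$name[1:2], c("cold", "hot"))
  # then name
  nm <- rank_candidates(list(mk("zeta", -2, 130), mk("alpha", -2, 130)))
  expect_identical(nm$name[1:2], c("alpha", "zeta"))
  # mixed window/threshold contexts refuse to rank
  other <- assess_coformer("o", -3, 150, "solid", process_window(80, 200))
  expect_error(rank_candidates(list(mk("a", -3, 150), other)), "context")
})

test_that("ranking matches a brute-force sort oracle on a seeded library", {
  set.seed(31)
  n <- 30
  tab <- data.frame(
    name = sprintf("c%02d", seq_len(n)),
    h_ex = round(stats::runif(n, -5, 2), 1), # rounding forces ties
    melting_point_C = round(stats::runif(n, 60, 300), -1),
    state_flag = sample(c("solid", "solid", "solid", "liquid"), n,
                        replace = TRUE))
  tab$melting_point_C[tab$state_flag == "liquid"] <- NA
  ass <- assess_candidates(tab, win)
  ranked <- rank_candidates(ass)
  keep <- !grepl("^excluded", ass$promise_class)
  bf <- ass[keep, ]
  bf <- bf[order(bf$h_ex, bf$melting_point, bf$name), ]
  expect_identical(ranked$name[seq_len(nrow(bf))], bf$name)
  expect_setequal(ranked$rank[!grepl("^excluded", ranked$promise_class)],
                  seq_len(nrow(bf)))
  expect_true(all(is.na(ranked$rank[grepl("^excluded",
                                          ranked$promise_class)])))
})

test_that("the exported map is deterministic and count-conserving", {
  mk <- function(name, hx, tm) assess_coformer(name, hx, tm, "solid", win)
  ass <- rank_candidates(list(mk("a", -3.1, 180), mk("b", -2.5, 140),
                              mk("c", 0.4, 150)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_map(ass, f1, win)
  export_map(ass, f2, win)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(utils::read.csv(f1)), 3)

  # empty assessment list: header-only CSV
  empty <- assess_candidates(
    data.frame(name = character(0), h_ex = numeric(0),
               melting_point_C = numeric(0), state_flag = character(0)),
    win)
  f3 <- withr::local_tempfile(fileext = ".csv")
  fig <- withr::local_tempfile(fileext = ".pdf")
  export_map(empty, f3, win, plot_file = fig)
  expect_equal(length(readLines(f3)), 1L)
  expect_true(file.exists(fig))

  # figure emission for a populated map
  fig2 <- withr::local_tempfile(fileext = ".png")
  export_map(ass, f1, win, plot_file = fig2)
  expect_gt(file.info(fig2)$size, 0)
})
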