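# A 20-window fixture scored by hand. Geometry: fs = 100 Hz, 10-sample
# windows stepping by 10 (no overlap), window i covers [10(i-1), 10i).
# Ground truth: "hand close" ramps over [20, 40), holds over [40, 100),
# decays over [100, 120); "hand open" ramps [140, 160), holds [160, 195).
# Window phases (1-based):
#   1-2 rest | 3-4 transient(close) | 5-10 steady(close)
#   11-12 transient(close decay) | 13-14 rest | 15-16 transient(open)
#   17-19 steady(open) | 20 transient(open: straddles the hold end at 195)
fixture_truth <- data.frame(
  motion = c("hand close", "hand close", "hand close",
             "hand open", "hand open"),
  start = c(20L, 40L, 100L, 140L, 160L),
  end = c(40L, 100L, 120L, 160L, 195L),
  phase = c("transient", "steady", "transient", "transient", "steady"),
  stringsAsFactors = FALSE)

fixture_stream <- function(outputs) {
  structure(data.frame(window_start = seq(0L, 190L, by = 10L),
                       raw_class = outputs, mav_mv = 0.3,
                       output = outputs, stringsAsFactors = FALSE),
            fs = 100, window_samples = 10L, step = 10L,
            class = c("decision_stream", "data.frame"))
}

test_that("a perfect stream scores 1.0 steady accuracy, 0 transient error", {
  perfect <- c("STILL", "STILL", "hand close", "hand close",
               rep("hand close", 6L), "hand close", "hand close",
               "STILL", "STILL", "hand open", "hand open",
               rep("hand open", 3L), "hand open")
  m <- score_stream(fixture_stream(perfect), fixture_truth)
  expect_equal(m$steady_accuracy, 1)
  expect_equal(m$transient_error_rate, 0)
  expect_equal(unname(m$n_windows),
               c(20L, 9L, 7L, 4L))   # total, steady, transient, rest
})

test_that("an all-STILL stream has zero accuracy, full transient stillness", {
  m <- score_stream(fixture_stream(rep(STILL, 20L)), fixture_truth)
  expect_equal(m$steady_accuracy, 0)
  expect_equal(m$still_rate_transient, 1)
  expect_equal(m$transient_error_rate, 0)
})

test_that("a mixed stream reproduces the hand-counted fixture metrics", {
  out <- c("hand open",   # w1  rest
           "STILL",       # w2  rest
           "hand open",   # w3  transient(close): WRONG
           "hand close",  # w4  transient(close): allowed
           "hand close", "hand close", "hand open",  # w5-7 steady: 2 right
           "STILL",       # w8  steady: wrong for accuracy
           "hand close", "hand close",   # w9-10 steady: right
           "STILL",       # w11 transient: still
           "wrist rotation",  # w12 transient(close): WRONG
           "STILL", "STILL",  # w13-14 rest
           "STILL",       # w15 transient(open): still
           "hand open",   # w16 transient(open): allowed
           "hand open", "STILL", "hand open",  # w17-19 steady: 2 right
           "hand close")  # w20 transient(open): WRONG
  m <- score_stream(fixture_stream(out), fixture_truth)
  # steady windows: w5..w10 (6) + w17..w19 (3) = 9; correct: w5,w6,w9,w10,
  # w17,w19 = 6
  expect_equal(m$steady_accuracy, 6 / 9)
  # transient windows: w3,w4,w11,w12,w15,w16,w20 = 7; wrong: w3,w12,w20 = 3
  expect_equal(m$transient_error_rate, 3 / 7)
  # STILL among transient: w11, w15 = 2
  expect_equal(m$still_rate_transient, 2 / 7)
  # confusion rows (steady only) sum to per-motion steady counts
  expect_equal(unname(rowSums(m$confusion)), c(6L, 3L),
               ignore_attr = TRUE)
  expect_equal(m$confusion["hand close", "STILL"], 1L, ignore_attr = TRUE)
  # conservation: phases partition the stream
  expect_equal(sum(m$n_windows[c("steady", "transient", "rest")]),
               m$n_windows[["total"]])
})

test_that("windows straddling a steady boundary count as transient", {
  truth <- data.frame(motion = "hand close", start = 5L, end = 95L,
                      phase = "steady", stringsAsFactors = FALSE)
  ds <- fixture_stream(rep("hand close", 20L))
  m <- score_stream(ds, truth)
  # w1 straddles the start; w10 straddles the end at 95; w11+ are rest
  expect_equal(m$n_windows[["transient"]], 2L)
  expect_equal(m$n_windows[["steady"]], 8L)
  expect_equal(m$n_windows[["rest"]], 10L)
})

test_that("percent increase reproduces the published score arithmetic", {
  expect_equal(unname(percent_increase(c(Control = 9.3, ST = 16))),
               (16 - 9.3) / 9.3 * 100)
  expect_equal(unname(percent_increase(c(Control = 9.3, L3 = 11))),
               (11 - 9.3) / 9.3 * 100)
  expect_equal(unname(percent_increase(c(Control = 9.3, X = 9.3))), 0)
  expect_error(percent_increase(c(Control = 0, X = 5)), "baseline")
  expect_error(percent_increase(c(A = 1), baseline = "B"), "not among")
})

test_that("percent increase is linear and antisymmetric about the baseline", {
  b <- 9.3
  x <- seq(2, 20, by = 1.7)
  p <- vapply(x, function(v)
    unname(percent_increase(c(Control = b, c = v))), numeric(1L))
  expect_equal(p, 100 * (x - b) / b)
  for (delta in c(0.5, 2, 7))
    expect_equal(unname(percent_increase(c(Control = b, c = b + delta))),
                 -unname(percent_increase(c(Control = b, c = b - delta))))
})

test_that("trial-level ARAT scores aggregate to condition totals", {
  scores <- expand.grid(condition = c("Control", "ST"), task = 1:3,
                        trial = 1:3, stringsAsFactors = FALSE)
  scores$score <- ifelse(scores$condition == "ST", 3L,
                         ifelse(scores$task == 1L, 2L, 1L))
  tot <- arat_totals(scores)
  expect_equal(unname(tot["ST"]), 9)          # 3 tasks x mean 3
  expect_equal(unname(tot["Control"]), 4)     # 2 + 1 + 1
  bad <- scores
  bad$score[1L] <- 5L
  expect_error(arat_totals(bad), "0..3")
})
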